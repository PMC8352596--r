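---
title: "Methylation dynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation dynamics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

methdyn analyses bisulfite-sequencing methylomes across developmental
stages and genotypes. This vignette is the package's own account of the
models it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## The differential-methylation model

A cytosine observed in $S$ pooled samples gives a $2 \times S$ table of
methylated and unmethylated read counts. With $M = \sum_i m_i$,
$N = \sum_i n_i$ and expected cells $e_{1i} = n_i M / N$,
$e_{2i} = n_i (N - M)/N$, the test statistic is

$$\mathrm{rms} = \sqrt{\frac{1}{2S} \sum_{\text{cells}}
  \left(\frac{o - e}{N}\right)^2},$$

zero exactly when every sample shows the pooled proportion $M/N$, and
invariant to sample order and to swapping the methylated/unmethylated
rows. The normalisation constant is a convention: any monotone variant
yields identical p-values because the permutation null uses the same
statistic.

The null holds both margins fixed: $M$ methylated labels are allocated
among $N$ reads partitioned into groups of sizes $n_i$, i.e. a
multivariate hypergeometric draw. When the number of distinct margin-fixed
tables is at most `exact_limit` (default $10^5$) the tail probability is
enumerated exactly; for two samples the statistic is monotone in
$|k - e_{11}|$ (with $k$ the methylated reads landing in sample 1), so the
exact tail reduces to a two-tailed hypergeometric sum and is vectorised
across the genome. Monte-Carlo mode draws $P$ tables by sequential
conditional hypergeometric sampling and reports
$p = (1 + \#\{\text{stat} \ge \text{obs}\})/(P+1)$, which keeps $p > 0$
and makes the resolution floor $1/(P+1)$; the default $P = 1000$ keeps
that floor well below the 0.01 working FDR.

Benjamini–Hochberg runs in one genome-wide batch per context class —
one FDR statement per class, matching how a single genome-wide catalog is
reported. Sites failing the coverage rule ($n_i \ge 4$ in every pooled
sample by default; a pooled-coverage variant is a flag) are not tested at
all rather than tested and discarded, so the BH denominator only counts
testable sites.

Design choices that were genuinely open:

* **CG strand handling.** Complementary CG cytosines are symmetric, and a
  caller could pool them before testing. By default each strand's
  cytosine is tested independently — the conservative reading of testing
  "each available cytosine" — and pooling is left to the caller via
  `pool_replicates()` on strand-collapsed tables if wanted.
* **Replicate pooling.** Counts from biological replicates of a condition
  are summed site-wise (`pool_replicates()`) before testing, not modelled
  as a hierarchy. This trades replicate-level dispersion modelling for
  the exact conditional null; it is the right trade at the shallow
  coverages typical of embryo methylomes.
* **Context classes.** CHG and CHH are tested and collapsed separately,
  both under the non-CG chaining threshold.

## DMR construction

DMCs are chained when consecutive sites (same class, any strand) lie
within 500 bp; chains need $\ge 8$ members for CG and $\ge 4$ for non-CG
to become DMRs. A DMR spans first to last member cytosine with a
half-open end at last position + 1 — no padding, because no padding rule
is principled without a smoothing model. `merge_dmr_sets()` union-merges
overlapping *or book-ended* intervals (the convention of interval
`merge` tools), and merged DMRs are re-scored across all samples as
weighted methylation, $\sum m / \sum n$. `overlap_summary()` counts
merged overlap events between two catalogs and reports them as a
percentage of $n_A + n_B$ by default (183 events between catalogs of
1185 and 1398 print as 7.1%); a union denominator is selectable.

## Weighted methylation and coverage rules

Weighted methylation is always the coverage-weighted rate
$\sum m / \sum n$, never a mean of per-site rates. Undefined rates (no
covered sites, or fewer informative sites than `min_sites`) propagate as
`NA` and are excluded pairwise downstream — zero-filling would bias every
average toward hypomethylation. Two distinct printed coverage filters are
kept apart deliberately: the TE rule (≥ 5 cytosines covered by ≥ 4 reads,
`mode = "sites"`) and the expressed-gene rule (≥ 5 reads pooled over a
gene's CHG sites, `mode = "reads"`). The second is the looser reading of
"≥ 5 reads overlapping CHG sites"; both interpretations are selectable
and the choice is a documented argument, not a constant.

## Metagene profiles and percentiles

Regions are rescaled to `n_up`/`n_body`/`n_down` bins (defaults 10/20/10;
the flank width of 1.5 kb is standard, bin counts are a package choice —
flank bins are fixed-width, body bins fractional). Minus-strand regions
are reversed so bin 1 is always 5' upstream; a strand-flipped region set
therefore yields exactly the reversed profile, which the tests assert.
Regions with a body shorter than `n_body` bp are skipped and counted
rather than given sub-bp bins. Per-bin means ignore undefined cells; in
per-gene difference matrices, undefined bins are zero-imputed (with a
per-row imputation count kept as an attribute) because k-means needs
complete rows — a zero difference is the least-informative completion.

Centromere-distance percentiles tile the genome into 1-kb bins, take the
per-bin methylation difference, and rank bins by the distance from bin
midpoint to centromere midpoint (the midpoint anchor is a declared
choice; the analysis only needs a monotone distance). Ties break by
(chromosome, start) so the 100 equal-count percentiles are deterministic.
Fewer than 100 covered bins is an error suggesting larger bins, not a
silent degenerate split.

## Clustering and co-expression

Per-gene CHG difference profiles are clustered with Lloyd's algorithm
from k-means++ seeding, best of `n_init = 25` restarts, deterministic
given a seed. Raw k-means labels are arbitrary, so clusters are
relabelled 1..k by ascending mean row-mean: cluster 1 is always the
unaffected group and cluster k the strongly hypermethylated one, making
identities stable across seeds and runs. If there are fewer distinct
profiles than clusters the assignment is forced rather than fitted.

Expression profiles are row-max normalised (`relative_levels()`) before
Euclidean distances: on raw TPM the distance is dominated by absolute
magnitude, and the analyses of interest compare trajectory *shapes*. A
raw-scale mode exists. The seed-set centroid ranks all genes (seeds
included, by default — the published convention ranks "all protein-coding
genes"; exclusion is a flag) with ties broken by gene id. The permutation
baseline draws `set_size` genes without replacement per iteration,
independently across iterations, and records per-sample medians; its
grand median converges to the population per-sample median, which both
the tests and the acceptance script measure in units of the resampling
standard error. Trajectory correlations are plain Pearson with
t-distribution p-values, reported unadjusted — the analyses make a
handful of planned comparisons, not a scan.

## Enrichment

The primary enrichment statistic is the gene-level hypergeometric tail
over a caller-supplied universe (never hard-coded: printed p-values in
this literature often leave the universe ambiguous, so the operation
refuses to guess). The base-pair interval variant
(`interval_overlap_test()`) union-merges both sides, partitions the
genome into query-only / reference-only / both / neither base pairs and
applies Fisher's test to that table. Treating base pairs as exchangeable
units ignores their spatial autocorrelation, so this is documented as an
approximation — kept for comparability with genome-background interval
Fisher tools, not recommended as the primary statistic.
`associate_dmrs_genes()` links a DMR to a gene when it lies within 1.5 kb
of the gene body, classifying upstream/downstream strand-aware with the
gap distance; with `flank = 0` it reduces to plain intersection.

## The synthetic-data generator

The generator's defaults are the study conditions the tests and the
acceptance script run under:

* **Genome**: 2 chromosomes × 2 Mb plus a 0.1 Mb unmethylated control
  chromosome; a pericentromeric compartment of 0.3 of each chromosome
  around the centromere; 400 genes on the arms, 300 TEs of which 80% are
  pericentromeric; features never overlap. Desk scale: the full pipeline
  runs in seconds to minutes.
* **Methylome**: cytosine densities 8/8/24 per kb for CG/CHG/CHH (the
  genomic ratio ≈ 1:1:3, at an absolute density high enough that a 2-kb
  gene has ~16 CHG sites for binned profiles). Baselines: TE
  CG/CHG/CHH = 0.85/0.60/0.10; genic CG = 0.20 with a linear 0.5×–1.5×
  5'→3' ramp (gene-body methylation with its 3' bias — declared shape,
  not fitted); genic CHG/CHH = 0.02; intergenic background 0.10/0.05/0.03.
  Coverage is Poisson(λ = 20) per site; reads are Binomial(n, rate); the
  control chromosome methylates at 1 − 0.99.
* **Planted effects** (`mutant_vs_wt`): CHG hyper-DMRs on 40 genes
  (delta +0.45, 3'-ramped) and 20 pericentromeric TEs (+0.35), two
  replicates per genotype that the pipeline pools before testing —
  pooling replicates is the procedure the pipeline itself prescribes, and
  at pooled depth ~40 a +0.35–0.45 delta is comfortably detectable while
  single-replicate depth 20 would sit at the edge of power. The
  expression contrast down-regulates exactly the DMR-bearing genes
  2.5-fold, above the 2-fold DE threshold.
* **Series** (`wildtype_series`): four stage methylomes (fb, eh, bc, mg)
  whose planted CG-DMR deltas are proportional to the cell-cycle
  expression archetype (peaking early, collapsing at maturity), plus a
  broad +0.12 pericentromeric CG gain at the mature-green stage, which is
  what the centromere-percentile analysis detects.
* **Expression**: 10 stages; a 25-gene module shares the archetype with
  log-normal noise (sd 0.10 on the log scale); background genes follow
  independent log-scale random walks (sd 0.35 per step) around
  log-normal base levels.

Cytosine *positions* are fixed by a separate `site_seed` shared across a
study's samples, so sites line up between conditions; read noise varies
by sample seed. Everything is reproducible from (spec, seed), and truth
files make each downstream stage's recovery measurable.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (mapping bias, M-bias,
PCR duplicates), sub-context preferences within CHG (CWG vs CCG),
TE family structure, spatial autocorrelation of methylation beyond the
planted regions, replicate-level biological dispersion beyond binomial
sampling, and any coupling between methylation and expression other than
the planted fold-changes. Recovery rates on this generator measure the
pipeline's correctness, not its power on real embryo methylomes.

## Numerical choices and degenerate inputs

* Tail comparisons use a 10⁻¹² slack (`stat >= obs - eps`) so ties count
  as extreme — the conservative convention for permutation tests.
* The exact/Monte-Carlo switch counts distinct margin-fixed tables with a
  polynomial-coefficient DP before deciding; it never enumerates first.
* `collapse_dmrs` on an empty DMC set, `metaprofile` on an all-short
  region set, `centromere_percentiles` with < 100 covered bins, a missing
  control chromosome, and `k > n_genes` are all explicit errors or typed
  empty results, never silent zeros.
* Percentages print at the precision such numbers are printed: integers
  at ≥ 10%, one decimal below.

## Problem sizes

The test-suite and acceptance runs use the generator defaults above
(4.1 Mb genome, ~164k cytosines per sample, 4 methylomes per scenario);
the exact-test oracle sweeps all two-sample tables with N ≤ 20 and the
hypergeometric oracle all universes N ≤ 25. These sizes were chosen so a
full run stays in the minutes range on one core while every statistic is
exercised at genome scale rather than on toy vectors alone.

## Known limitations

* The RMS permutation test conditions on margins; it does not model
  biological replicate dispersion (no beta-binomial), so FDR statements
  are about sampling noise given pooled counts.
* DMR boundaries are chain extents; no smoothing or boundary refinement.
* The interval-background Fisher variant ignores spatial autocorrelation
  (see above).
* `context_class()` trusts the caller's trinucleotide column; there is no
  FASTA-based recomputation, by design — the pipeline operates on caller
  output.
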