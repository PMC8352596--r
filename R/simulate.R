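# Seeded generators for a desk-scale study: a small genome with a TE-dense
# pericentromeric compartment and gene-dense arms, per-context methylomes
# with Poisson coverage and binomial reads, planted differential regions,
# and expression matrices with a planted co-varying module. Every stage of
# the pipeline is testable against the planted truth.

#' Genome specification for the synthetic generator
#'
#' Defaults describe a 2 x 2 Mb genome plus a 0.1 Mb unmethylated control
#' chromosome, ~400 genes on the chromosome arms and ~300 TEs placed
#' preferentially in the pericentromeric compartment.
#'
#' @param chrom_lengths named vector of nuclear chromosome lengths (bp).
#' @param centromere_mid named vector of centromere midpoints (0-based bp).
#' @param control_chrom,control_length unmethylated control chromosome.
#' @param pericent_frac fraction of each chromosome around the centromere
#'   forming the TE-dense compartment (default 0.3, i.e. +/- 0.15 L).
#' @param n_genes,n_tes feature counts (genome-wide).
#' @param te_pericent_prop fraction of TEs placed pericentromerically.
#' @param gene_len,te_len length ranges (bp).
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths = c(Chr1 = 2e6, Chr2 = 2e6),
                        centromere_mid = c(Chr1 = 1e6, Chr2 = 1e6),
                        control_chrom = "ChrC", control_length = 1e5,
                        pericent_frac = 0.3,
                        n_genes = 400L, n_tes = 300L,
                        te_pericent_prop = 0.8,
                        gene_len = c(1000L, 3000L),
                        te_len = c(500L, 3000L)) {
  stopifnot(all(names(chrom_lengths) == names(centromere_mid)),
            pericent_frac > 0, pericent_frac < 1)
  structure(list(chrom_lengths = chrom_lengths,
                 centromere_mid = centromere_mid,
                 control_chrom = control_chrom, control_length = control_length,
                 pericent_frac = pericent_frac,
                 n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
                 te_pericent_prop = te_pericent_prop,
                 gene_len = gene_len, te_len = te_len),
            class = "genome_spec")
}

# non-overlapping placement of n intervals with lengths in len_range inside
# the union of allowed windows (data.table chrom,start,end); `occ` carries
# per-chromosome occupied ranges so feature types never overlap each other
place_features <- function(windows, n, len_range, prefix, kind,
                           occ = list(), max_tries = 50L) {
  placed <- vector("list", n)
  wsize <- windows$end - windows$start
  for (i in seq_len(n)) {
    done <- FALSE
    for (t in seq_len(max_tries)) {
      w <- sample.int(nrow(windows), 1L, prob = wsize)
      len <- sample(len_range[1L]:len_range[2L], 1L)
      lo <- windows$start[w]; hi <- windows$end[w] - len
      if (hi <= lo) next
      s <- lo + sample.int(hi - lo, 1L)
      ch <- windows$chrom[w]
      ir <- IRanges::IRanges(s + 1L, s + len)
      if (!is.null(occ[[ch]]) &&
          length(IRanges::findOverlaps(ir, occ[[ch]])) > 0L) next
      occ[[ch]] <- if (is.null(occ[[ch]])) ir else c(occ[[ch]], ir)
      placed[[i]] <- data.table(chrom = ch, start = s, end = s + len,
                                strand = sample(c("+", "-"), 1L))
      done <- TRUE
      break
    }
    if (!done) stop("infeasible feature density: could not place ", kind, " ", i)
  }
  feats <- rbindlist(placed)
  rs <- region_set(chrom = feats$chrom, start = feats$start, end = feats$end,
                   strand = feats$strand,
                   label = sprintf("%s%04d", prefix, seq_len(n)), kind = kind)
  list(regions = rs, occ = occ)
}

#' Generate a synthetic genome layout
#'
#' Places TEs preferentially in the pericentromeric compartment and genes
#' on the arms, with random strands; fully deterministic given `seed`.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @return list: `genes`, `tes` ([region_set()]s), `centromeres`
#'   (data.table chrom, mid), `genome_sizes` (named, incl. control
#'   chromosome), `pericentromeric` ([region_set()] of compartment
#'   windows), `spec`.
#' @export
generate_genome <- function(spec = genome_spec(), seed = 1L) {
  set.seed(seed)
  chroms <- names(spec$chrom_lengths)
  half <- spec$pericent_frac / 2
  peri <- data.table(chrom = chroms,
                     start = as.integer(spec$centromere_mid - half * spec$chrom_lengths),
                     end = as.integer(spec$centromere_mid + half * spec$chrom_lengths))
  arms <- rbindlist(lapply(chroms, function(ch) {
    p <- peri[chrom == ch]
    data.table(chrom = ch, start = c(0L, p$end),
               end = c(p$start, as.integer(spec$chrom_lengths[[ch]])))
  }))
  gp <- place_features(arms, spec$n_genes, spec$gene_len, "GENE", "gene")
  genes <- gp$regions
  tes <- if (spec$n_tes > 0L) {
    n_peri <- round(spec$n_tes * spec$te_pericent_prop)
    occ <- gp$occ          # arm TEs must not overlap genes
    t1 <- if (n_peri > 0L) {
      r <- place_features(peri, n_peri, spec$te_len, "TEP", "TE", occ)
      occ <- r$occ; r$regions
    }
    t2 <- if (spec$n_tes - n_peri > 0L)
      place_features(arms, spec$n_tes - n_peri, spec$te_len, "TEA", "TE",
                     occ)$regions
    tt <- rbindlist(Filter(Negate(is.null), list(t1, t2)))
    region_set(chrom = tt$chrom, start = tt$start, end = tt$end,
               strand = tt$strand, label = tt$label, kind = "TE")
  } else region_set()
  sizes <- c(spec$chrom_lengths,
             setNames(spec$control_length, spec$control_chrom))
  list(genes = genes, tes = tes,
       centromeres = data.table(chrom = chroms,
                                mid = as.numeric(spec$centromere_mid)),
       genome_sizes = sizes,
       pericentromeric = region_set(chrom = peri$chrom, start = peri$start,
                                    end = peri$end, kind = "other",
                                    label = paste0("peri_", peri$chrom)),
       spec = spec)
}

#' Methylome specification for the synthetic generator
#'
#' Baseline weighted-methylation rates per compartment and context mimic a
#' plant methylome: heavily methylated TEs (high CG/CHG), 3'-biased genic
#' CG gene-body methylation, near-zero genic CHG/CHH in wild type, and a
#' low intergenic background. Per-site coverage is Poisson(`lambda`);
#' reads are Binomial(n, rate). Planted effects are rows of `planted`
#' (chrom, start, end, strand, context, condition, delta, bias3p, kind).
#'
#' @param baselines list of named rate vectors for `te`, `gene`,
#'   `intergenic` (names CG/CHG/CHH).
#' @param densities sites per kb by context (ratio ~ 1:1:3).
#' @param lambda mean per-site read coverage.
#' @param conversion_true true bisulfite conversion rate; the control
#'   chromosome methylates at 1 - this.
#' @param gene_cg_bias3p apply the 0.5x-1.5x 5'->3' ramp to genic CG.
#' @param planted data.table of planted effects (may be empty).
#' @param site_seed seed fixing cytosine positions; shared across all
#'   conditions of one study so sites line up between samples.
#' @return list of class `methylome_spec`.
#' @export
methylome_spec <- function(baselines = list(
                             te = c(CG = 0.85, CHG = 0.60, CHH = 0.10),
                             gene = c(CG = 0.20, CHG = 0.02, CHH = 0.02),
                             intergenic = c(CG = 0.10, CHG = 0.05, CHH = 0.03)),
                           densities = c(CG = 8, CHG = 8, CHH = 24),
                           lambda = 20,
                           conversion_true = 0.99,
                           gene_cg_bias3p = TRUE,
                           planted = NULL,
                           site_seed = 101L) {
  if (is.null(planted))
    planted <- data.table(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          context = character(), condition = character(),
                          delta = numeric(), bias3p = logical(),
                          kind = character())
  stopifnot(lambda >= 0, conversion_true >= 0, conversion_true <= 1)
  structure(list(baselines = baselines, densities = densities,
                 lambda = lambda, conversion_true = conversion_true,
                 gene_cg_bias3p = gene_cg_bias3p, planted = planted,
                 site_seed = as.integer(site_seed)),
            class = "methylome_spec")
}

# fixed cytosine site map shared by all samples of a study
generate_sites <- function(genome, mspec) {
  set.seed(mspec$site_seed)
  out <- list()
  for (ch in names(genome$genome_sizes)) {
    len <- genome$genome_sizes[[ch]]
    for (ctx in CONTEXTS) {
      cnt <- round(mspec$densities[[ctx]] * len / 1000)
      if (cnt == 0L) next
      pos <- sort(sample.int(len, cnt)) - 1L
      out[[paste(ch, ctx)]] <- data.table(
        chrom = ch, pos = pos,
        strand = sample(c("+", "-"), cnt, replace = TRUE), context = ctx)
    }
  }
  sites <- rbindlist(out)
  setorder(sites, chrom, pos, strand)   # matches cytosine_table ordering
  sites
}

# true per-site rates for one condition (before read noise)
true_rates <- function(sites, genome, mspec, condition) {
  bl <- mspec$baselines
  rate <- unname(bl$intergenic[sites$context])
  sgr <- sites_to_gr(sites)
  mark <- function(regions) {
    if (nrow(regions) == 0L) return(NULL)
    GenomicRanges::findOverlaps(sgr, regions_to_gr(regions), ignore.strand = TRUE)
  }
  ramp_frac <- function(qi, ri, regions) {
    fr <- (sites$pos[qi] - regions$start[ri]) / (regions$end - regions$start)[ri]
    ifelse(regions$strand[ri] == "-", 1 - fr, fr)
  }
  ht <- mark(genome$tes)
  if (!is.null(ht) && length(ht))
    rate[S4Vectors::queryHits(ht)] <- bl$te[sites$context[S4Vectors::queryHits(ht)]]
  hg <- mark(genome$genes)
  if (!is.null(hg) && length(hg)) {
    qi <- S4Vectors::queryHits(hg); ri <- S4Vectors::subjectHits(hg)
    base <- bl$gene[sites$context[qi]]
    if (mspec$gene_cg_bias3p) {
      iscg <- sites$context[qi] == "CG"
      base[iscg] <- base[iscg] * (0.5 + ramp_frac(qi[iscg], ri[iscg], genome$genes))
    }
    rate[qi] <- base
  }
  # planted effects for this condition
  keep_pl <- mspec$planted$condition == condition
  pl <- mspec$planted[keep_pl, ]
  if (nrow(pl)) {
    hp <- GenomicRanges::findOverlaps(sgr, regions_to_gr(pl), ignore.strand = TRUE)
    if (length(hp)) {
      qi <- S4Vectors::queryHits(hp); ri <- S4Vectors::subjectHits(hp)
      ok <- sites$context[qi] == pl$context[ri]
      qi <- qi[ok]; ri <- ri[ok]
      d <- pl$delta[ri]
      scale <- ifelse(pl$bias3p[ri], 0.5 + ramp_frac(qi, ri, pl), 1)
      rate[qi] <- rate[qi] + d * scale
    }
  }
  ctl <- sites$chrom == genome$spec$control_chrom
  rate[ctl] <- 1 - mspec$conversion_true
  pmin(pmax(rate, 0), 1)
}

#' Generate one synthetic methylome
#'
#' Cytosine positions are fixed by `spec$site_seed` (shared across the
#' study's samples); per-site coverage is Poisson(`lambda`) and methylated
#' reads Binomial(n, true rate), where the true rate is the compartment
#' baseline plus any planted delta for `condition` (3'-ramped where
#' flagged), clipped to [0, 1]. The control chromosome methylates at
#' 1 - `conversion_true` in all contexts.
#'
#' @param genome output of [generate_genome()].
#' @param spec a [methylome_spec()].
#' @param condition sample label matched against `spec$planted$condition`.
#' @param seed integer seed for the read-level noise.
#' @return a [cytosine_table()] with attribute `true_rate`.
#' @export
generate_methylome <- function(genome, spec = methylome_spec(),
                               condition = "wt", seed = 1L) {
  sites <- generate_sites(genome, spec)
  rate <- true_rates(sites, genome, spec, condition)
  set.seed(seed)
  n <- rpois(nrow(sites), spec$lambda)
  m <- rbinom(nrow(sites), n, rate)
  tab <- cytosine_table(sites$chrom, sites$pos, sites$strand, sites$context,
                        m, n)
  # cytosine_table re-sorts; sites are already (chrom,pos) sorted and the
  # strand tie-break keeps order stable only if unique positions
  setattr(tab, "true_rate", rate)
  tab
}

#' Expression specification for the synthetic generator
#'
#' A developmental series (default: the 10-stage flower-to-leaf series) in
#' TPM-like units. A planted "cell-cycle" module shares an early-peaking,
#' maturation-declining archetype; background genes follow independent
#' smooth random trajectories. Optionally, planted down-regulated genes
#' get a >= 2-fold reduction in mutant contrast columns.
#'
#' @param stages stage labels, in developmental order.
#' @param archetype module trajectory (TPM), length = #stages.
#' @param module_size genes in the co-varying module.
#' @param noise_sd sd of the log-normal multiplicative noise on module
#'   rows (log scale).
#' @param down_fold fold-reduction applied to planted down-regulated
#'   genes in mutant columns (>= 2 to be callable at the DE threshold).
#' @param n_reps replicate columns per contrast condition.
#' @param contrast_stage stage at which the wt/mutant contrast is taken.
#' @return list of class `expression_spec`.
#' @export
expression_spec <- function(stages = c("fb", "pg", "gl", "eh", "lh",
                                       "et", "lt", "bc", "mg", "lf"),
                            archetype = c(40, 85, 100, 95, 70, 50, 30, 15, 4, 10),
                            module_size = 25L,
                            noise_sd = 0.10,
                            down_fold = 2.5,
                            n_reps = 3L,
                            contrast_stage = "bc") {
  stopifnot(length(archetype) == length(stages), all(archetype >= 0))
  structure(list(stages = stages, archetype = archetype,
                 module_size = as.integer(module_size), noise_sd = noise_sd,
                 down_fold = down_fold, n_reps = as.integer(n_reps),
                 contrast_stage = contrast_stage),
            class = "expression_spec")
}

#' Generate a synthetic expression matrix
#'
#' @param genome output of [generate_genome()] (gene ids come from it).
#' @param spec an [expression_spec()].
#' @param seed integer seed.
#' @param down_genes gene ids to down-regulate in mutant columns (usually
#'   genes carrying planted hyper-DMRs); empty for a pure series.
#' @return matrix genes x columns (stage series, plus
#'   `<stage>_wt_r*` / `<stage>_mut_r*` contrast columns when
#'   `down_genes` given) with attributes `module_genes`, `down_genes`.
#' @export
generate_expression <- function(genome, spec = expression_spec(), seed = 1L,
                                down_genes = character()) {
  set.seed(seed)
  ids <- genome$genes$label
  ng <- length(ids)
  ns <- length(spec$stages)
  if (spec$module_size > ng) stop("module larger than gene count")
  module <- sort(sample(ids, spec$module_size))
  base <- exp(rnorm(ng, log(40), 0.8))
  # smooth independent background trajectories (random walk on log scale)
  expr <- matrix(0, ng, ns, dimnames = list(ids, spec$stages))
  steps <- matrix(rnorm(ng * ns, 0, 0.35), ng, ns)
  expr[] <- base * exp(t(apply(steps, 1L, cumsum)))
  mi <- match(module, ids)
  noise <- matrix(exp(rnorm(length(mi) * ns, 0, spec$noise_sd)),
                  length(mi), ns)
  expr[mi, ] <- rep(spec$archetype, each = length(mi)) * noise
  if (length(down_genes)) {
    stopifnot(all(down_genes %in% ids))
    cs <- spec$contrast_stage
    wt_cols <- matrix(rep(expr[, cs], spec$n_reps), ng) *
      matrix(exp(rnorm(ng * spec$n_reps, 0, 0.05)), ng)
    mut_cols <- matrix(rep(expr[, cs], spec$n_reps), ng) *
      matrix(exp(rnorm(ng * spec$n_reps, 0, 0.05)), ng)
    mut_cols[match(down_genes, ids), ] <-
      mut_cols[match(down_genes, ids), ] / spec$down_fold
    colnames(wt_cols) <- paste0(cs, "_wt_r", seq_len(spec$n_reps))
    colnames(mut_cols) <- paste0(cs, "_mut_r", seq_len(spec$n_reps))
    expr <- cbind(expr, wt_cols, mut_cols)
  }
  structure(expr, module_genes = module, down_genes = down_genes)
}

#' Generate a complete synthetic study bundle on disk
#'
#' Two scenarios:
#' \describe{
#'   \item{`mutant_vs_wt`}{two replicates each of "wt" and "mutant" at the
#'     contrast stage; planted mutant-specific CHG hyper-DMRs on 40 genes
#'     (delta +0.45, 3'-ramped) and 20 pericentromeric TEs (delta +0.35),
#'     an expression contrast with the DMR-bearing genes down-regulated,
#'     and truth files.}
#'   \item{`wildtype_series`}{one methylome per stage (fb, eh, bc, mg)
#'     with planted CG DMRs whose deltas track the cell-cycle archetype,
#'     a broad pericentromeric CG gain in "mg", and the 10-stage
#'     expression series with the planted module.}
#' }
#'
#' @param scenario `"mutant_vs_wt"` or `"wildtype_series"`.
#' @param seed integer master seed; all randomness derives from it.
#' @param out_dir directory for the bundle (created if needed); `NULL`
#'   keeps everything in memory.
#' @param genome_seed seed for the genome layout.
#' @param gspec a [genome_spec()]; planted-feature counts scale down
#'   automatically on small genomes.
#' @return list: `genome`, `samples` ([sample_set()]), `expression`,
#'   `mspec`, `truth` (list with `dmrs`, `module_genes`, `down_genes`),
#'   `files` (paths written, or NULL).
#' @export
generate_full_study <- function(scenario = c("mutant_vs_wt", "wildtype_series"),
                                seed = 1L, out_dir = NULL,
                                genome_seed = NULL, gspec = genome_spec()) {
  scenario <- match.arg(scenario)
  if (is.null(genome_seed)) genome_seed <- seed + 1000L
  genome <- generate_genome(gspec, seed = genome_seed)
  set.seed(seed)
  if (scenario == "mutant_vs_wt") {
    gsel <- sort(sample.int(nrow(genome$genes),
                            min(40L, nrow(genome$genes) %/% 2L)))
    tsel_pool <- which(grepl("^TEP", genome$tes$label))
    tsel <- sort(sample(tsel_pool, min(20L, length(tsel_pool) %/% 2L)))
    g <- genome$genes[gsel]; t <- genome$tes[tsel]
    planted <- rbind(
      data.table(chrom = g$chrom, start = g$start, end = g$end,
                 strand = g$strand, context = "CHG", condition = "mutant",
                 delta = 0.45, bias3p = TRUE, kind = "genic"),
      data.table(chrom = t$chrom, start = t$start, end = t$end,
                 strand = t$strand, context = "CHG", condition = "mutant",
                 delta = 0.35, bias3p = FALSE, kind = "TE"))
    mspec <- methylome_spec(planted = planted, site_seed = seed + 2000L)
    tabs <- list(
      wt_r1 = generate_methylome(genome, mspec, "wt", seed + 11L),
      wt_r2 = generate_methylome(genome, mspec, "wt", seed + 12L),
      mut_r1 = generate_methylome(genome, mspec, "mutant", seed + 13L),
      mut_r2 = generate_methylome(genome, mspec, "mutant", seed + 14L))
    samples <- sample_set(tabs,
                          stage = rep("bc", 4L),
                          genotype = c("wt", "wt", "mutant", "mutant"))
    down <- g$label
    expr <- generate_expression(genome, expression_spec(), seed + 3000L,
                                down_genes = down)
    truth <- list(
      dmrs = region_set(chrom = planted$chrom, start = planted$start,
                        end = planted$end, strand = planted$strand,
                        label = paste0("planted_", seq_len(nrow(planted))),
                        kind = "DMR", context = planted$context,
                        delta = planted$delta),
      module_genes = attr(expr, "module_genes"),
      down_genes = down)
  } else {
    stages <- c("fb", "eh", "bc", "mg")
    esp <- expression_spec()
    arch_at <- esp$archetype[match(stages, esp$stages)]
    gsel <- sort(sample.int(nrow(genome$genes),
                            min(30L, nrow(genome$genes) %/% 2L)))
    g <- genome$genes[gsel]
    stage_rows <- rbindlist(lapply(seq_along(stages), function(i) {
      data.table(chrom = g$chrom, start = g$start, end = g$end,
                 strand = g$strand, context = "CG", condition = stages[i],
                 delta = 0.25 * arch_at[i] / max(esp$archetype),
                 bias3p = FALSE, kind = "genic")
    }))
    peri <- genome$pericentromeric
    peri_rows <- data.table(chrom = peri$chrom, start = peri$start,
                            end = peri$end, strand = ".", context = "CG",
                            condition = "mg", delta = 0.12, bias3p = FALSE,
                            kind = "compartment")
    mspec <- methylome_spec(planted = rbind(stage_rows, peri_rows),
                            site_seed = seed + 2000L)
    tabs <- setNames(lapply(seq_along(stages), function(i)
      generate_methylome(genome, mspec, stages[i], seed + 10L + i)), stages)
    samples <- sample_set(tabs, stage = stages,
                          genotype = rep("wt", length(stages)))
    expr <- generate_expression(genome, esp, seed + 3000L)
    truth <- list(
      dmrs = region_set(chrom = g$chrom, start = g$start, end = g$end,
                        strand = g$strand,
                        label = paste0("planted_", seq_len(nrow(g))),
                        kind = "DMR", context = "CG",
                        delta = 0.25),
      module_genes = attr(expr, "module_genes"),
      down_genes = character(),
      stage_deltas = data.table(stage = stages,
                                delta = 0.25 * arch_at / max(esp$archetype)))
  }
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    write_regions(genome$genes, fp("genes.bed"))
    if (nrow(genome$tes)) write_regions(genome$tes, fp("tes.bed"))
    fwrite(genome$centromeres, fp("centromeres.tsv"), sep = "\t")
    fwrite(data.table(chrom = names(genome$genome_sizes),
                      length = as.integer(genome$genome_sizes)),
           fp("genome_sizes.tsv"), sep = "\t")
    for (id in names(samples$tables))
      write_cytosine_table(samples$tables[[id]], fp(paste0("allc_", id, ".tsv")))
    fwrite(data.table(gene = rownames(expr), as.data.table(unclass(expr))),
           fp("expression.tsv"), sep = "\t")
    write_regions(truth$dmrs, fp("truth_dmrs.bed"))
    fwrite(data.table(gene = truth$module_genes), fp("truth_module.tsv"), sep = "\t")
    fwrite(data.table(gene = truth$down_genes), fp("truth_down_genes.tsv"), sep = "\t")
    files <- list.files(out_dir, full.names = TRUE)
  }
  list(genome = genome, samples = samples, expression = expr,
       mspec = mspec, truth = truth, files = files)
}
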