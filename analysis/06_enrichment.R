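#!/usr/bin/env Rscript
# Stage 6: DMR-gene association and overlap enrichment.
#
# A gene and a DMR are associated when the DMR falls within 1.5 kb of the
# gene body. Down-regulated genes (>= 2-fold in the expression contrast)
# are tested for enrichment among DMR-associated genes with the
# hypergeometric/Fisher test over the expressed-gene universe, and the
# base-pair interval variant tests called DMRs against the planted truth
# with the nuclear genome as background.

suppressMessages(library(methdyn))
dir.create("results", showWarnings = FALSE)

seed <- 7L
st <- generate_full_study("mutant_vs_wt", seed = seed)
pooled <- pool_replicates(st$samples,
                          list(wt = c("wt_r1", "wt_r2"),
                               mut = c("mut_r1", "mut_r2")))
dmcs <- call_dmcs(pooled, "CHG", fdr = 0.01, cov_min = 4L, seed = seed)
dmrs <- collapse_dmrs(dmcs, "nonCG", window = 500L)

links <- associate_dmrs_genes(dmrs, st$genome$genes, flank = 1500L)
data.table::fwrite(links, "results/06_dmr_gene_links.tsv", sep = "\t")
message(nrow(links), " DMR-gene links (",
        length(unique(links$gene)), " genes, ",
        length(unique(links$dmr)), " DMRs)")

# down-regulated genes from the expression contrast (>= 2-fold)
expr <- st$expression
wt_cols <- grep("_wt_r", colnames(expr))
mut_cols <- grep("_mut_r", colnames(expr))
fc <- rowMeans(expr[, wt_cols]) / rowMeans(expr[, mut_cols])
down <- names(fc)[fc >= 2]
universe <- rownames(expr)
dmr_genes <- unique(links$gene)

enr <- gene_set_overlap_test(down, dmr_genes, universe)
data.table::fwrite(
  data.table::data.table(overlap = enr$a, down_only = enr$b,
                         dmr_only = enr$c, neither = enr$d,
                         odds_ratio = enr$odds_ratio,
                         p_one_sided = enr$p_one_sided,
                         p_two_sided = enr$p_two_sided),
  "results/06_down_gene_enrichment.tsv", sep = "\t")
message("down-regulated x DMR-associated: ", enr$a, " of ", length(down),
        " down genes (", summarize_fraction(enr$a, length(down)),
        "% of total), one-sided p = ", signif(enr$p_one_sided, 3))

nuclear <- st$genome$genome_sizes[names(st$genome$genome_sizes) != "ChrC"]
iv <- interval_overlap_test(dmrs, st$truth$dmrs, nuclear)
message("called-vs-planted interval Fisher (bp units): overlap ", iv$a,
        " bp, p = ", signif(iv$p_one_sided, 3))
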