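small_gspec <- function(n_genes = 80L, n_tes = 60L) {
  genome_spec(chrom_lengths = c(Chr1 = 4e5, Chr2 = 4e5),
              centromere_mid = c(Chr1 = 2e5, Chr2 = 2e5),
              n_genes = n_genes, n_tes = n_tes)
}

strip_truth <- function(tab) {
  x <- as.data.frame(tab)
  attr(x, "true_rate") <- NULL
  x
}

test_that("genome generation is seeded, compartmentalised, and validates density", {
  g1 <- generate_genome(small_gspec(), seed = 1L)
  g2 <- generate_genome(small_gspec(), seed = 1L)
  g3 <- generate_genome(small_gspec(), seed = 2L)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$tes, g2$tes)
  expect_false(identical(g1$genes, g3$genes))

  # >= 80% of TEs placed within 0.15 L of the centromere midpoint
  mid <- g1$centromeres$mid[match(g1$tes$chrom, g1$centromeres$chrom)]
  frac_near <- mean(abs((g1$tes$start + g1$tes$end) / 2 - mid) <= 0.15 * 4e5)
  expect_gte(frac_near, 0.8)
  # genes live on the arms
  gmid <- g1$centromeres$mid[match(g1$genes$chrom, g1$centromeres$chrom)]
  expect_true(all(abs((g1$genes$start + g1$genes$end) / 2 - gmid) >= 0.13 * 4e5))

  none <- generate_genome(small_gspec(n_tes = 0L), seed = 1L)
  expect_equal(nrow(none$tes), 0L)
  expect_error(generate_genome(genome_spec(chrom_lengths = c(Chr1 = 1e4),
                                           centromere_mid = c(Chr1 = 5e3),
                                           n_genes = 500L, n_tes = 0L), 1L),
               "infeasible")
})

test_that("methylomes match spec baselines within binomial error and honour planted deltas", {
  genome <- generate_genome(small_gspec(), seed = 3L)
  te <- genome$tes[1:15]
  planted <- data.table::data.table(chrom = te$chrom, start = te$start,
                                    end = te$end, strand = te$strand,
                                    context = "CHG", condition = "mut",
                                    delta = 0.3, bias3p = FALSE, kind = "TE")
  msp <- methylome_spec(planted = planted, site_seed = 7L)
  wt <- generate_methylome(genome, msp, "wt", seed = 1L)
  mut <- generate_methylome(genome, msp, "mut", seed = 2L)

  # same site map across conditions; different read noise
  expect_identical(strip_truth(wt)[, 1:4], strip_truth(mut)[, 1:4])
  expect_false(identical(wt$m, mut$m))
  # same seed twice is identical
  expect_identical(strip_truth(wt),
                   strip_truth(generate_methylome(genome, msp, "wt", seed = 1L)))

  # marginal TE CHG methylation ~ 0.60 within 3 binomial SEs
  other_te <- genome$tes[16:nrow(genome$tes)]
  rm_ <- region_methylation(wt, other_te, "CHG")
  pooled_rate <- sum(rm_$m_sum) / sum(rm_$n_sum)
  se <- sqrt(0.6 * 0.4 / sum(rm_$n_sum))
  expect_lt(abs(pooled_rate - 0.6), 3 * se + 0.01)

  # planted delta recovered as a rate difference of ~0.3 at lambda = 20
  wt_r <- region_methylation(wt, te, "CHG")
  mut_r <- region_methylation(mut, te, "CHG")
  d <- sum(mut_r$m_sum) / sum(mut_r$n_sum) - sum(wt_r$m_sum) / sum(wt_r$n_sum)
  expect_lt(abs(d - 0.3), 0.03)

  # genic CHG near zero in wild type
  grm <- region_methylation(wt, genome$genes, "CHG")
  expect_lt(sum(grm$m_sum) / sum(grm$n_sum), 0.05)

  # conversion-rate round trip on the control chromosome
  expect_lt(abs(conversion_rate(wt, "ChrC") - 0.99), 0.005)
})

test_that("genic CG carries a 3'-biased gene-body profile", {
  genome <- generate_genome(small_gspec(), seed = 4L)
  wt <- generate_methylome(genome, methylome_spec(site_seed = 5L), "wt", seed = 1L)
  mp <- metaprofile(wt, genome$genes, "CG")
  body <- (mp$n_up + 1):(mp$n_up + mp$n_body)
  last5 <- tail(body, 5L); first5 <- head(body, 5L)
  expect_gt(mean(mp$values[last5]), mean(mp$values[first5]))
})

test_that("lambda = 0 gives an empty-coverage but valid table", {
  genome <- generate_genome(small_gspec(), seed = 5L)
  tab <- generate_methylome(genome, methylome_spec(lambda = 0), "wt", seed = 1L)
  expect_true(all(tab$n == 0L))
  expect_true(all(tab$m == 0L))
})

test_that("expression generator plants the module and the fold-changes exactly", {
  genome <- generate_genome(small_gspec(), seed = 6L)
  spec0 <- expression_spec(noise_sd = 0)
  e0 <- generate_expression(genome, spec0, seed = 2L)
  mod <- attr(e0, "module_genes")
  expect_equal(length(mod), 25L)
  for (g in mod[1:3])
    expect_equal(unname(e0[g, spec0$stages]), spec0$archetype)

  down <- genome$genes$label[1:10]
  e1 <- generate_expression(genome, expression_spec(), seed = 2L,
                            down_genes = down)
  wt_cols <- grep("_wt_r", colnames(e1)); mut_cols <- grep("_mut_r", colnames(e1))
  fc <- rowMeans(e1[, wt_cols]) / rowMeans(e1[, mut_cols])
  flagged <- names(fc)[fc >= 2]
  expect_setequal(flagged, down)
  expect_true(all(e1 >= 0))
})

test_that("full-study bundles are deterministic and carry usable truth files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_full_study("mutant_vs_wt", seed = 3L, out_dir = d1,
                            gspec = small_gspec())
  s2 <- generate_full_study("mutant_vs_wt", seed = 3L, out_dir = d2,
                            gspec = small_gspec())
  for (f in basename(s1$files))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_true(all(c("genes.bed", "expression.tsv", "truth_dmrs.bed") %in%
                    basename(s1$files)))
  back <- read_cytosine_table(file.path(d1, "allc_wt_r1.tsv"), "allc")
  expect_equal(as.data.frame(back), strip_truth(s1$samples$tables$wt_r1))

  ws <- generate_full_study("wildtype_series", seed = 4L)
  expect_equal(names(ws$samples$tables), c("fb", "eh", "bc", "mg"))
  arch <- expression_spec()$archetype
  # module trajectory peaks early then declines toward maturity
  expect_gt(max(arch[1:4]), max(arch[8:9]))
})
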