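test_that("constant methylation yields a flat metaprofile", {
  pos <- seq(0L, 4999L, 10L)
  tab <- ct("Chr1", pos, "+", "CG", m = rep(2L, length(pos)), n = rep(4L, length(pos)))
  mp <- metaprofile(tab, rg("Chr1", 1500L, 3500L), "CG",
                    n_up = 5L, n_body = 10L, n_down = 5L, flank_bp = 1500L)
  expect_equal(unname(mp$values), rep(0.5, 20L))
  expect_equal(mp$n_regions, 1L)
})

test_that("strand-flipped regions give the mirrored profile", {
  set.seed(21)
  pos <- seq(0L, 7999L, 7L)
  n <- rpois(length(pos), 12) + 1L
  # asymmetric signal: methylation rises along the chromosome
  m <- rbinom(length(pos), n, pos / 8000)
  tab <- ct("Chr1", pos, "+", "CHG", m = m, n = n)
  plus <- rg("Chr1", 2000L, 6000L, "+")
  minus <- rg("Chr1", 2000L, 6000L, "-")
  mp_p <- metaprofile(tab, plus, "CHG", 4L, 8L, 4L, 1000L)
  mp_m <- metaprofile(tab, minus, "CHG", 4L, 8L, 4L, 1000L)
  expect_equal(unname(mp_m$values), rev(unname(mp_p$values)))
})

test_that("metaprofile averages per-bin across regions ignoring undefined cells", {
  t1 <- rbind(ct("Chr1", seq(100L, 999L, 9L), "+", "CG",
                 m = rep(1L, 100L), n = rep(5L, 100L)),          # rate 0.2
              ct("Chr2", seq(100L, 999L, 9L), "+", "CG",
                 m = rep(2L, 100L), n = rep(5L, 100L)))          # rate 0.4
  regions <- region_set(chrom = c("Chr1", "Chr2"), start = 100L, end = 1000L,
                        strand = "+", label = c("g1", "g2"))
  mp <- metaprofile(t1, regions, "CG", 2L, 4L, 2L, 200L)
  body <- 3:6
  expect_equal(unname(mp$values[body]), rep(0.3, 4L))
  expect_equal(unname(mp$spread[body]), rep(sd(c(0.2, 0.4)), 4L))
  # order invariance
  mp2 <- metaprofile(t1, regions[2:1], "CG", 2L, 4L, 2L, 200L)
  expect_equal(mp2$values, mp$values)
})

test_that("short regions are skipped and an all-skip set errors", {
  tab <- ct("Chr1", c(5L, 10L), "+", "CG", m = c(1L, 1L), n = c(2L, 2L))
  tiny <- rg("Chr1", 4L, 8L)                     # 4 bp < n_body = 10
  expect_error(metaprofile(tab, tiny, "CG", 2L, 10L, 2L, 100L), "skipped")
  both <- region_set(chrom = "Chr1", start = c(0L, 4L), end = c(60L, 8L),
                     strand = "+", label = c("ok", "tiny"))
  mp <- metaprofile(tab, both, "CG", 2L, 10L, 2L, 100L)
  expect_equal(mp$n_regions, 1L)
  expect_equal(mp$n_skipped, 1L)
})

test_that("difference profiles are exactly zero for identical tables", {
  set.seed(33)
  pos <- seq(0L, 9999L, 11L)
  n <- rpois(length(pos), 8) + 1L
  tab <- ct("Chr1", pos, "+", "CHG", m = rbinom(length(pos), n, 0.3), n = n)
  genes <- region_set(chrom = "Chr1", start = c(1000L, 5000L),
                      end = c(3000L, 7000L), strand = c("+", "-"),
                      label = c("g1", "g2"), kind = "gene")
  d <- difference_profiles(tab, tab, genes, "CHG", 3L, 6L, 3L, 500L)
  expect_true(all(d == 0))
  expect_equal(rownames(d), c("g1", "g2"))
})

test_that("genes failing the coverage filter are absent from the profile matrix", {
  pos <- seq(1000L, 2999L, 50L)
  tabA <- rbind(ct("Chr1", pos, "+", "CHG", m = rep(1L, 40L), n = rep(3L, 40L)),
                ct("Chr2", 1500L, "+", "CHG", m = 1L, n = 4L))   # 4 reads < 5
  genes <- region_set(chrom = c("Chr1", "Chr2"), start = 1000L, end = 3000L,
                      strand = "+", label = c("covered", "thin"), kind = "gene")
  d <- difference_profiles(tabA, tabA, genes, "CHG", 2L, 4L, 2L, 500L,
                           min_reads = 5L)
  expect_equal(rownames(d), "covered")
})

test_that("planted 3'-biased genic hypermethylation shows up with the right polarity", {
  genome <- generate_genome(genome_spec(chrom_lengths = c(Chr1 = 4e5),
                                        centromere_mid = c(Chr1 = 2e5),
                                        n_genes = 60L, n_tes = 30L), seed = 2L)
  g <- genome$genes[1:10]
  planted <- data.table::data.table(chrom = g$chrom, start = g$start, end = g$end,
                                    strand = g$strand, context = "CHG",
                                    condition = "mut", delta = 0.5,
                                    bias3p = TRUE, kind = "genic")
  msp <- methylome_spec(planted = planted, site_seed = 9L)
  wt <- generate_methylome(genome, msp, "wt", seed = 4L)
  mut <- generate_methylome(genome, msp, "mut", seed = 5L)
  d <- difference_profiles(mut, wt, genome$genes, "CHG")
  pl <- rownames(d) %in% g$label
  expect_gt(mean(d[pl, 11:30]), 0.15)
  expect_lt(abs(mean(d[!pl, 11:30])), 0.05)
  # 3' body bins exceed 5' body bins for the planted genes
  expect_gt(mean(d[pl, 26:30]), mean(d[pl, 11:15]))
})

test_that("centromere percentiles are deterministic and detect pericentromeric gain", {
  set.seed(55)
  len <- 3e5
  pos <- sort(sample.int(len, 6000L)) - 1L
  n <- rpois(6000L, 15) + 1L
  near <- abs(pos - 1.5e5) < 5e4
  base <- rbinom(6000L, n, 0.3)
  tabB <- ct("Chr1", pos, "+", "CG", m = base, n = n)
  gain <- rbinom(6000L, n, ifelse(near, 0.5, 0.3))
  tabA <- ct("Chr1", pos, "+", "CG", m = gain, n = n)
  cen <- data.frame(chrom = "Chr1", mid = 1.5e5)
  p1 <- centromere_percentiles(tabA, tabB, "CG", 1000L, cen, c(Chr1 = len))
  p2 <- centromere_percentiles(tabA, tabB, "CG", 1000L, cen, c(Chr1 = len))
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 100L)
  expect_gt(p1$median[1], p1$median[100])

  # constant difference -> flat percentiles
  flat <- centromere_percentiles(tabA, tabA, "CG", 1000L, cen, c(Chr1 = len))
  expect_true(all(abs(flat$median) < 1e-12))
  expect_error(centromere_percentiles(tabA, tabB, "CG", 1000L, cen,
                                      c(Chr1 = 5e4)),
               "covered bins")
})
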