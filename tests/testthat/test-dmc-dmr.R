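test_that("RMS statistic matches hand-computed tables and degenerate cases", {
  expect_equal(rms_statistic(c(4L, 4L), c(4L, 4L)), 0)
  # all four cells deviate by 2, N = 8: sqrt((1/4) * 4 * (2/8)^2) = 0.25
  expect_equal(rms_statistic(c(4L, 0L), c(4L, 4L)), 0.25)
  # proportional margins at unequal depths
  expect_equal(rms_statistic(c(1L, 2L, 4L), c(2L, 4L, 8L)), 0)
  expect_error(rms_statistic(c(0L, 0L), c(0L, 0L)), "undefined")
})

test_that("RMS statistic is invariant to sample order and row swap", {
  set.seed(11)
  for (i in 1:20) {
    S <- sample(2:5, 1L)
    n <- rpois(S, 8) + 1L
    m <- rbinom(S, n, runif(1))
    s0 <- rms_statistic(m, n)
    perm <- sample(S)
    expect_equal(rms_statistic(m[perm], n[perm]), s0)
    expect_equal(rms_statistic(n - m, n), s0)   # methylated/unmethylated swap
  }
})

test_that("exact permutation p equals brute-force enumeration over margin-fixed tables", {
  # worked table: (4,4) vs (0,4) -> statistic 0.25, p = 2/70
  p <- permutation_pvalue(c(4L, 0L), c(4L, 4L))
  expect_equal(attr(p, "mode"), "exact")
  expect_equal(as.numeric(p), 2 / 70)
  expect_equal(as.numeric(permutation_pvalue(c(3L, 3L), c(4L, 4L))), 1)

  set.seed(5)
  for (i in 1:40) {
    n1 <- sample(1:10, 1L); n2 <- sample(1:10, 1L)
    m1 <- sample(0:n1, 1L); m2 <- sample(0:n2, 1L)
    expect_equal(as.numeric(permutation_pvalue(c(m1, m2), c(n1, n2))),
                 oracle_two_sample_p(m1, n1, m2, n2), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo mode converges on the exact tail probability", {
  exact <- 2 / 70
  p1 <- permutation_pvalue(c(4L, 0L), c(4L, 4L), P = 2000L, seed = 1L,
                           exact_limit = 0)
  p2 <- permutation_pvalue(c(4L, 0L), c(4L, 4L), P = 2000L, seed = 99L,
                           exact_limit = 0)
  expect_equal(attr(p1, "mode"), "mc")
  mc_se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(as.numeric(p1) - exact), 4 * mc_se + 1e-3)
  expect_lt(abs(as.numeric(p2) - exact), 4 * mc_se + 1e-3)
  expect_error(permutation_pvalue(c(1L, 0L), c(2L, 2L), P = 0L), "P must be")
})

test_that("multi-sample exact enumeration agrees with Monte Carlo", {
  m <- c(5L, 1L, 3L); n <- c(6L, 6L, 6L)
  pe <- permutation_pvalue(m, n)
  expect_equal(attr(pe, "mode"), "exact")
  pm <- permutation_pvalue(m, n, P = 4000L, seed = 3L, exact_limit = 0)
  expect_lt(abs(as.numeric(pe) - as.numeric(pm)),
            4 * sqrt(as.numeric(pe) / 4000) + 2e-3)
})

test_that("DMC calling enforces coverage, BH, and the single-test edge case", {
  # single tested site with exact p = 2/70 > fdr 0.01 -> not a DMC
  ss <- two_sample_set(100L, m1 = 4L, n1 = 4L, m2 = 0L, n2 = 4L)
  res <- call_dmcs(ss, "CHG", fdr = 0.01, cov_min = 4L)
  expect_equal(nrow(res), 1L)
  expect_false(res$is_dmc)
  expect_equal(res$q, res$p)                      # BH with one test keeps raw p
  expect_equal(res$`dir.s1`, 1)
  expect_equal(res$`dir.s2`, -1)

  # sites failing per-sample coverage are not tested
  ss2 <- two_sample_set(c(100L, 200L), m1 = c(4L, 1L), n1 = c(4L, 3L),
                        m2 = c(0L, 1L), n2 = c(4L, 8L))
  res2 <- call_dmcs(ss2, "CHG", cov_min = 4L)
  expect_equal(res2$pos, 100L)
  res3 <- call_dmcs(ss2, "CHG", cov_min = 4L, cov_rule = "pooled")
  expect_equal(nrow(res3), 2L)
  expect_warning(call_dmcs(ss2, "CG"), "no sites")
})

test_that("replicate pooling sums counts site-wise before testing", {
  r1 <- ct("Chr1", c(10L, 20L), "+", "CG", m = c(1L, 2L), n = c(2L, 4L))
  r2 <- ct("Chr1", c(10L, 30L), "+", "CG", m = c(1L, 1L), n = c(3L, 2L))
  pooled <- pool_replicates(sample_set(list(a = r1, b = r2)),
                            list(ab = c("a", "b")))
  tab <- pooled$tables$ab
  expect_equal(tab[tab$pos == 10L, ]$m, 2L)
  expect_equal(tab[tab$pos == 10L, ]$n, 5L)
  expect_equal(nrow(tab), 3L)
})

test_that("DMC chains collapse into DMRs under spacing and count thresholds", {
  # 8 CG DMCs spaced 50 bp -> one DMR spanning first to last + 1
  d8 <- fake_dmcs(seq(100L, 450L, 50L))
  dmr <- collapse_dmrs(d8, "CG", already_filtered = TRUE)
  expect_equal(nrow(dmr), 1L)
  expect_equal(c(dmr$start, dmr$end), c(100L, 451L))
  expect_equal(dmr$n_dmcs, 8L)

  # 7 in one chain: below the CG >= 8 threshold
  expect_equal(nrow(collapse_dmrs(fake_dmcs(seq(100L, 400L, 50L)), "CG",
                                  already_filtered = TRUE)), 0L)

  # 4 CHG DMCs split by a 501-bp gap -> chains of 2 and 2, no DMR
  d4 <- fake_dmcs(c(100L, 200L, 701L, 801L))
  expect_equal(nrow(collapse_dmrs(d4, "nonCG", already_filtered = TRUE)), 0L)
  # same four within 500 bp spacing -> one nonCG DMR
  d4b <- fake_dmcs(c(100L, 200L, 700L, 800L))
  expect_equal(nrow(collapse_dmrs(d4b, "nonCG", already_filtered = TRUE)), 1L)

  # chains never span chromosomes
  d_two <- rbind(fake_dmcs(c(100L, 150L), "Chr1"), fake_dmcs(c(160L, 210L), "Chr2"))
  expect_equal(nrow(collapse_dmrs(d_two, "nonCG", already_filtered = TRUE,
                                  min_dmcs = 2L)), 2L)
})

test_that("DMR set union-merge handles overlap, book-ends, and is idempotent", {
  a <- rg("Chr1", 100L, 200L, ".", "a", "DMR")
  b <- rg("Chr1", 150L, 300L, ".", "b", "DMR")
  m <- merge_dmr_sets(list(a, b))
  expect_equal(c(m$start, m$end), c(100L, 300L))

  c_ <- rg("Chr1", 200L, 250L, ".", "c", "DMR")
  m2 <- merge_dmr_sets(list(rg("Chr1", 100L, 200L, ".", "a", "DMR"), c_))
  expect_equal(c(m2$start, m2$end), c(100L, 250L))      # book-ended

  d1 <- rg("Chr1", 100L, 200L, ".", "d1", "DMR")
  d2 <- rg("Chr1", 300L, 400L, ".", "d2", "DMR")
  m3 <- merge_dmr_sets(list(d1, d2))
  expect_equal(m3$start, c(100L, 300L))
  # idempotent and order-independent
  expect_equal(merge_dmr_sets(list(m3))$start, m3$start)
  expect_equal(merge_dmr_sets(list(d2, d1))$start, m3$start)

  xa <- rg("Chr1", 0L, 10L, ".", "x", "DMR"); data.table::setattr(xa, "context_class", "CG")
  xb <- rg("Chr1", 5L, 15L, ".", "y", "DMR"); data.table::setattr(xb, "context_class", "nonCG")
  expect_error(merge_dmr_sets(list(xa, xb)), "mixed context")
})

test_that("overlap summary counts merged events over the combined total", {
  s <- rg("Chr1", 100L, 200L, ".", "s", "DMR")
  ident <- overlap_summary(s, rg("Chr1", 100L, 200L, ".", "t", "DMR"))
  expect_equal(ident$n_overlap, 1L)
  expect_equal(ident$pct_of_total, 50.0)

  disj <- overlap_summary(s, rg("Chr1", 300L, 400L, ".", "t", "DMR"))
  expect_equal(disj$n_overlap, 0L)
  expect_equal(disj$pct_of_total, 0)
})
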