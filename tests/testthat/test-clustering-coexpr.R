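test_that("relative levels divide rows by their maxima", {
  x <- rbind(a = c(2, 4, 8), b = c(5, 5, 5), c = c(0, 0, 0))
  r <- relative_levels(x)
  expect_equal(unname(r["a", ]), c(0.25, 0.5, 1.0))
  expect_equal(unname(r["b", ]), c(1, 1, 1))
  expect_equal(unname(r["c", ]), c(0, 0, 0))
})

test_that("k-means separates planted groups and orders clusters by severity", {
  set.seed(8)
  flat <- matrix(rnorm(100 * 10, 0, 0.01), 100)
  high <- matrix(rnorm(80 * 10, 0.5, 0.01), 80)
  prof <- rbind(flat, high)
  rownames(prof) <- paste0("g", seq_len(nrow(prof)))
  cl <- kmeans_partition(prof, k = 2L, seed = 4L)
  truth <- rep(1:2, c(100, 80))
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
  # severity relabel: cluster 1 is the flat group
  expect_true(all(cl$cluster[1:100] == 1L))
  expect_equal(cl$sizes, c(100L, 80L))

  # deterministic under a fixed seed, invariant to row order up to labels
  cl2 <- kmeans_partition(prof, k = 2L, seed = 4L)
  expect_identical(cl$cluster, cl2$cluster)
  perm <- sample(nrow(prof))
  cl3 <- kmeans_partition(prof[perm, ], k = 2L, seed = 9L)
  expect_identical(cl3$cluster[rownames(prof)], cl$cluster)
})

test_that("four planted archetypes are recovered in severity order", {
  set.seed(13)
  nb <- 20L
  ramp <- seq(0.5, 1.5, length.out = nb)
  arch <- list(zero = rep(0, nb), low = rep(0.06, nb),
               moderate = rep(0.18, nb), high = 0.45 * ramp)
  prof <- do.call(rbind, lapply(seq_along(arch), function(i)
    matrix(rep(arch[[i]], each = 60), 60) + rnorm(60 * nb, 0, 0.02)))
  rownames(prof) <- paste0("g", seq_len(240))
  truth <- rep(1:4, each = 60)
  cl <- kmeans_partition(prof, k = 4L, seed = 2L)
  expect_gte(mclust::adjustedRandIndex(cl$cluster, truth), 0.9)
  # modal assigned label increases with planted severity
  modal <- vapply(1:4, function(g)
    as.integer(names(which.max(table(cl$cluster[truth == g])))), integer(1L))
  expect_equal(modal, 1:4)
})

test_that("degenerate identical rows cluster deterministically", {
  prof <- matrix(0.2, 30, 5, dimnames = list(paste0("g", 1:30), NULL))
  cl1 <- kmeans_partition(prof, k = 2L, seed = 1L)
  cl2 <- kmeans_partition(prof, k = 2L, seed = 1L)
  expect_identical(cl1$cluster, cl2$cluster)
  expect_error(kmeans_partition(prof[1:2, ], k = 3L), "exceeds")
})

test_that("cluster proportions reproduce printed percentages", {
  expect_equal(cluster_proportions(1439L, 22637L), 6.4)
  expect_equal(cluster_proportions(7882L, 22637L), 34.8)
  expect_equal(cluster_proportions(0L, 100L), 0.0)
})

test_that("centroid neighbours rank by Euclidean distance with stable ties", {
  expr <- rbind(A = c(1, 2, 3), B = c(1, 2, 4), C = c(5, 1, 0))
  nb <- centroid_neighbors(expr, "A", top_n = 3L, normalize = FALSE)
  dB <- sqrt(sum((expr["B", ] - expr["A", ])^2))
  dC <- sqrt(sum((expr["C", ] - expr["A", ])^2))
  expect_equal(nb$ranked[gene == "B", distance], dB)
  expect_equal(nb$ranked[gene == "C", distance], dC)
  expect_equal(nb$ranked$gene, c("A", "B", "C"))
  expect_equal(nb$ranked$distance[1], 0)            # seed identical to centroid

  # all-identical rows: all distances equal, order = gene id (tie-break)
  same <- matrix(1, 4, 3, dimnames = list(c("d", "b", "a", "c"), NULL))
  nb2 <- centroid_neighbors(same, c("a", "b"), top_n = 4L)
  expect_equal(nb2$ranked$gene, c("a", "b", "c", "d"))
  expect_error(centroid_neighbors(same, "zz"), "zz")

  nb3 <- centroid_neighbors(expr, "A", top_n = 2L, normalize = FALSE,
                            include_seeds = FALSE)
  expect_false("A" %in% nb3$ranked$gene)
})

test_that("permutation baseline reproduces shared profiles and is seed-stable", {
  one <- matrix(rep(c(1, 3, 2), each = 40), 40,
                dimnames = list(paste0("g", 1:40), NULL))
  bl <- permutation_baseline(one, set_size = 10L, iterations = 50L, seed = 1L)
  expect_true(all(bl$medians[, 2] == 1))            # relative levels: max -> 1
  expect_equal(unname(bl$grand_median), c(1 / 3, 1, 2 / 3))

  set.seed(77)
  expr <- matrix(rexp(200 * 6), 200, dimnames = list(paste0("g", 1:200), NULL))
  b1 <- permutation_baseline(expr, 25L, 400L, seed = 1L)
  b2 <- permutation_baseline(expr, 25L, 400L, seed = 2L)
  expect_false(identical(b1$medians, b2$medians))
  expect_lt(max(abs(b1$grand_median - b2$grand_median)), 0.1)
  expect_error(permutation_baseline(expr, 300L), "exceeds")
})

test_that("a planted co-varying module is recovered against the baseline", {
  genome <- generate_genome(genome_spec(n_genes = 200L, n_tes = 0L), seed = 3L)
  expr <- generate_expression(genome, expression_spec(), seed = 5L)
  mod <- attr(expr, "module_genes")
  nb <- centroid_neighbors(expr, mod[1:4], top_n = 25L)
  expect_gte(sum(setdiff(mod, mod[1:4]) %in% nb$top), 20L)
  bl <- permutation_baseline(expr, 25L, 300L, seed = 6L)
  pop <- apply(relative_levels(expr), 2L, median)
  expect_true(all(abs(bl$grand_median - pop) <= 3 * bl$se))
})

test_that("trajectory correlation matches hand-computed Pearson values", {
  expect_equal(trajectory_correlation(1:5, 2 * (1:5) + 1)$r, 1.0)
  expect_equal(trajectory_correlation(1:5, -(1:5))$r, -1.0)
  tc <- trajectory_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(tc$r, 0.8)                            # cov 4/3 over sd^2 5/3
  expect_equal(tc$p, cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))$p.value)
  cz <- trajectory_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(cz$r) && cz$zero_variance)
  expect_error(trajectory_correlation(c(1, NA), c(2, 3)), "paired stages")
})
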