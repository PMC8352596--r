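# Expression-side analyses: relative (row-max-normalised) levels, k-means
# partitioning of methylation-difference profiles, centroid
# nearest-neighbour co-expression with a permutation baseline, and
# trajectory correlation.

#' Row-max normalised ("relative") expression levels
#'
#' Divides each gene row by its maximum so trajectories are comparable on a
#' [0, 1] scale regardless of absolute abundance. All-zero rows pass
#' through unchanged.
#'
#' @param expr numeric matrix, genes x samples (non-negative).
#' @return matrix of the same shape with rows in [0, 1].
#' @export
relative_levels <- function(expr) {
  stopifnot(is.matrix(expr), all(expr >= 0, na.rm = TRUE))
  mx <- apply(expr, 1L, max)
  out <- expr / ifelse(mx > 0, mx, 1)
  out
}

# k-means++ style seeding: first centre uniform, then each next centre
# drawn with probability proportional to squared distance to the nearest
# chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' Partition gene profiles with k-means
#'
#' Lloyd's algorithm from k-means++ style seeding, best of `n_init`
#' restarts by total within-cluster sum of squares; deterministic given
#' `seed`. Clusters are relabelled 1..k by ascending mean row-mean, so
#' cluster 1 is the least-changed (e.g. least hypermethylated) group and
#' cluster k the most affected — stable identities across seeds.
#'
#' @param profiles numeric matrix, genes x bins (e.g. from
#'   [difference_profiles()]).
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param n_init number of restarts (default 25).
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector), `k`, `seed`, `sizes`, `centers` (k x bins, relabelled),
#'   `tot_withinss`.
#' @export
kmeans_partition <- function(profiles, k = 4L, seed = 1L, n_init = 25L) {
  stopifnot(k >= 2L)
  n <- nrow(profiles)
  if (k > n) stop("k = ", k, " exceeds number of genes (", n, ")")
  set.seed(seed)
  ux <- unique(profiles)
  if (nrow(ux) < k) {
    # fewer distinct profiles than clusters: assignment is forced
    best <- list(cluster = match(data.frame(t(profiles)), data.frame(t(ux))),
                 centers = rbind(ux, matrix(NA_real_, k - nrow(ux), ncol(ux))),
                 tot.withinss = 0)
  } else {
    best <- NULL
    for (i in seq_len(n_init)) {
      ctr <- kmeanspp_centers(profiles, k)
      if (anyDuplicated(ctr)) next
      fit <- suppressWarnings(
        kmeans(profiles, centers = ctr, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best))
      stop("could not find ", k, " distinct initial centers")
  }
  sev <- tapply(rowMeans(profiles), best$cluster, mean)   # severity per raw label
  # relabel by ascending severity; ties (e.g. empty-degenerate fits) keep order
  new_of_old <- integer(k)
  present <- as.integer(names(sev))
  ord <- present[order(sev)]
  new_of_old[ord] <- seq_along(ord)
  missing_lab <- setdiff(seq_len(k), present)
  if (length(missing_lab))
    new_of_old[missing_lab] <- seq(length(ord) + 1L, k)
  cl <- new_of_old[best$cluster]
  names(cl) <- rownames(profiles)
  centers <- matrix(NA_real_, k, ncol(profiles))
  centers[new_of_old[present], ] <- best$centers[present, , drop = FALSE]
  structure(list(cluster = cl, k = k, seed = seed,
                 sizes = tabulate(cl, nbins = k),
                 centers = centers,
                 tot_withinss = best$tot.withinss),
            class = "cluster_assignment")
}

#' Cluster sizes as percentages of a gene universe
#'
#' @param assign a `cluster_assignment` from [kmeans_partition()], or an
#'   integer vector of per-cluster sizes.
#' @param universe_n size of the gene universe.
#' @return numeric vector of per-cluster percentages, rounded to 1 decimal.
#' @export
cluster_proportions <- function(assign, universe_n) {
  sizes <- if (inherits(assign, "cluster_assignment")) assign$sizes else assign
  stopifnot(universe_n >= max(sizes))
  round(100 * sizes / universe_n, 1)
}

#' Rank genes by Euclidean distance to a seed-set expression centroid
#'
#' The centroid is the per-sample mean of the seed genes' (relative)
#' profiles; every gene in the matrix is then ranked by Euclidean distance
#' to it. Ties are broken by gene id, so the ranking is deterministic.
#'
#' @param expr genes x samples matrix with rownames.
#' @param seed_genes character vector of seed gene ids (must be rows).
#' @param top_n how many nearest genes to report (default 25).
#' @param normalize apply [relative_levels()] first (default TRUE).
#' @param include_seeds keep seed genes in the ranking (default TRUE,
#'   i.e. all genes are ranked).
#' @return list: `ranked` (data.table gene, distance, rank), `top`
#'   (first `top_n` gene ids), `centroid` (per-sample vector).
#' @export
centroid_neighbors <- function(expr, seed_genes, top_n = 25L,
                               normalize = TRUE, include_seeds = TRUE) {
  missing_seeds <- setdiff(seed_genes, rownames(expr))
  if (length(missing_seeds))
    stop("seed gene(s) not in matrix: ", paste(missing_seeds, collapse = ", "))
  x <- if (normalize) relative_levels(expr) else expr
  centroid <- colMeans(x[seed_genes, , drop = FALSE])
  d <- sqrt(rowSums(sweep(x, 2L, centroid)^2))
  dt <- data.table(gene = rownames(x), distance = d)
  if (!include_seeds) dt <- dt[!gene %in% seed_genes]
  setorder(dt, distance, gene)
  dt[, rank := .I]
  list(ranked = dt[], top = dt$gene[seq_len(min(top_n, nrow(dt)))],
       centroid = centroid)
}

#' Permutation baseline of per-sample median profiles
#'
#' Draws `iterations` random gene sets of `set_size` (without replacement
#' within a draw, independent across draws) and records the per-sample
#' median of their (relative) profiles. The grand per-sample median of
#' these draws is the null expectation a planted co-expression module must
#' beat.
#'
#' @inheritParams centroid_neighbors
#' @param set_size genes per draw (default 25).
#' @param iterations number of draws (default 1000).
#' @param seed integer seed.
#' @return list: `medians` (iterations x samples matrix), `grand_median`
#'   (per-sample), `se` (per-sample sd of the draws).
#' @export
permutation_baseline <- function(expr, set_size = 25L, iterations = 1000L,
                                 seed = 1L, normalize = TRUE) {
  if (set_size > nrow(expr))
    stop("set_size (", set_size, ") exceeds gene count (", nrow(expr), ")")
  x <- if (normalize) relative_levels(expr) else expr
  set.seed(seed)
  med <- matrix(NA_real_, iterations, ncol(x))
  for (i in seq_len(iterations)) {
    rows <- sample.int(nrow(x), set_size)
    med[i, ] <- apply(x[rows, , drop = FALSE], 2L, median)
  }
  colnames(med) <- colnames(x)
  list(medians = med,
       grand_median = apply(med, 2L, median),
       se = apply(med, 2L, sd))
}

#' Pearson correlation between two developmental trajectories
#'
#' Pairwise-complete Pearson r with the usual t-distribution two-sided
#' p-value; used to relate DMR-methylation trajectories to transcript
#' trajectories across stages.
#'
#' @param x,y numeric vectors (matched stages).
#' @return list: `r`, `p`, `n` (pairs used). `r` is `NA` (flagged via
#'   `zero_variance = TRUE`) when either vector is constant.
#' @export
trajectory_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired stages, got ", length(x))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), zero_variance = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       zero_variance = FALSE)
}
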