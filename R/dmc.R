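# Differential methylation testing: a root-mean-square statistic on the
# 2 x S methylated/unmethylated contingency table of one cytosine across S
# pooled samples, with a margin-fixed permutation null (exact enumeration
# when tractable, Monte Carlo otherwise) and genome-wide BH control.

#' Root-mean-square statistic of a 2 x S methylation contingency table
#'
#' For S samples with methylated counts `m` and totals `n`, the table has
#' rows (methylated, unmethylated) and one column per sample. With
#' M = sum(m), N = sum(n) and expected cells e1i = n_i M / N,
#' e2i = n_i (N - M) / N, the statistic is
#' sqrt( (1/(2S)) * sum(((o - e)/N)^2) ) over all 2S cells. It is zero
#' exactly when every sample has the pooled proportion M/N, and is
#' invariant to sample order and to swapping the two rows.
#'
#' @param m integer vector of methylated counts (one per sample).
#' @param n integer vector of total counts.
#' @return the statistic (non-negative scalar).
#' @export
rms_statistic <- function(m, n) {
  stopifnot(length(m) == length(n), length(m) >= 2L, all(m <= n), all(m >= 0L))
  N <- sum(n)
  if (N == 0L) stop("all totals are zero; statistic undefined")
  S <- length(m)
  M <- sum(m)
  e1 <- n * M / N
  e2 <- n * (N - M) / N
  sqrt(sum(((m - e1) / N)^2 + ((n - m - e2) / N)^2) / (2 * S))
}

# number of tables (k vectors, 0 <= k_i <= n_i, sum = M) with both margins
# fixed; polynomial-coefficient DP
count_margin_tables <- function(n, M) {
  poly <- rep(1, n[1L] + 1L)                  # coefs of sum_k x^k, k=0..n1
  for (ni in n[-1L]) {
    nxt <- rep(0, min(length(poly) + ni, M + 1L))
    for (k in 0:ni) {
      lim <- min(length(poly), length(nxt) - k)
      if (lim >= 1L) nxt[(k + 1L):(k + lim)] <- nxt[(k + 1L):(k + lim)] + poly[1:lim]
    }
    poly <- nxt
    if (all(poly > .Machine$double.xmax / 1e6)) return(Inf)
  }
  if (M + 1L > length(poly)) 0 else poly[M + 1L]
}

# enumerate all margin-fixed tables recursively; returns matrix of k vectors
enumerate_tables <- function(n, M) {
  S <- length(n)
  rec <- function(i, rem) {
    if (i == S) {
      if (rem <= n[S]) return(matrix(rem, nrow = 1L)) else return(NULL)
    }
    lo <- max(0L, rem - sum(n[(i + 1L):S]))
    hi <- min(n[i], rem)
    if (lo > hi) return(NULL)
    do.call(rbind, lapply(lo:hi, function(k) {
      sub <- rec(i + 1L, rem - k)
      if (is.null(sub)) NULL else cbind(k, sub, deparse.level = 0)
    }))
  }
  rec(1L, M)
}

# statistic for each row of a k-vector matrix under fixed margins n, M
stat_for_tables <- function(K, n, M) {
  N <- sum(n)
  S <- length(n)
  e1 <- n * M / N
  dev2 <- sweep(K, 2L, e1)^2           # row-2 deviations are the negatives
  sqrt(rowSums(dev2) * 2 / N^2 / (2 * S))
}

#' Permutation p-value for the RMS statistic with both margins fixed
#'
#' The null conditions on both margins of the 2 x S table: M methylated
#' labels are allocated among N reads partitioned into groups of sizes
#' n_i (multivariate hypergeometric). When the number of distinct tables is
#' at most `exact_limit` the tail probability is computed by full
#' enumeration; otherwise `P` Monte-Carlo tables are drawn and
#' p = (1 + #\{stat_perm >= stat_obs\}) / (P + 1).
#'
#' @inheritParams rms_statistic
#' @param P number of Monte-Carlo permutations (>= 1).
#' @param seed optional integer seed for the Monte-Carlo branch.
#' @param exact_limit switch to exact enumeration when the number of
#'   distinct margin-fixed tables is at most this.
#' @return p-value in (0, 1]; attribute `"mode"` is "exact" or "mc".
#' @export
permutation_pvalue <- function(m, n, P = 1000L, seed = NULL, exact_limit = 1e5) {
  if (P < 1L) stop("P must be >= 1")
  obs <- rms_statistic(m, n)
  M <- sum(m); N <- sum(n); S <- length(n)
  eps <- 1e-12
  if (count_margin_tables(n, M) <= exact_limit) {
    K <- enumerate_tables(n, M)
    st <- stat_for_tables(K, n, M)
    lp <- lchoose(N, M)
    prob <- exp(rowSums(lchoose(matrix(n, nrow(K), S, byrow = TRUE), K)) - lp)
    p <- sum(prob[st >= obs - eps])
    return(structure(min(p, 1), mode = "exact"))
  }
  if (!is.null(seed)) set.seed(seed)
  K <- matrix(0L, P, S)
  rem_M <- rep(M, P)
  rem_N <- N
  for (i in seq_len(S - 1L)) {
    # draw k_i | remaining: white = rem_M, black = rem_N - rem_M, drawn = n[i]
    ki <- rhyper(P, m = rem_M, n = rem_N - rem_M, k = n[i])
    K[, i] <- ki
    rem_M <- rem_M - ki
    rem_N <- rem_N - n[i]
  }
  K[, S] <- rem_M
  st <- stat_for_tables(K, n, M)
  structure((1 + sum(st >= obs - eps)) / (P + 1), mode = "mc")
}

# vectorised exact p for the two-sample case: the statistic is monotone in
# |k - e1| where k = methylated reads in sample 1, so the tail is a
# hypergeometric two-tail. Inputs are equal-length vectors (one site each).
exact_pvalue_two_sample <- function(m1, n1, m2, n2) {
  M <- m1 + m2
  N <- n1 + n2
  e1 <- n1 * M / N
  d <- abs(m1 - e1)
  lo <- pmax(0L, M - n2)
  hi <- pmin(M, n1)
  width <- hi - lo + 1L
  idx <- rep.int(seq_along(m1), width)
  k <- unlist(lapply(seq_along(m1), function(i) lo[i]:hi[i]), use.names = FALSE)
  pk <- dhyper(k, m = n1[idx], n = n2[idx], k = M[idx])
  keep <- abs(k - e1[idx]) >= d[idx] - 1e-9
  pmin(as.vector(rowsum(pk * keep, idx)), 1)
}

#' Assemble a per-site count table across samples
#'
#' Joins the per-sample cytosine tables of a [sample_set()] on
#' (chrom, pos, strand) for one context class. Sites absent from a sample
#' get m = n = 0 there.
#'
#' @param samples a [sample_set()].
#' @param context "CG", "CHG" or "CHH".
#' @return data.table with chrom, pos, strand, context and per-sample
#'   columns `m.<id>`, `n.<id>`.
#' @export
build_site_table <- function(samples, context) {
  ids <- names(samples$tables)
  stopifnot(length(ids) >= 2L)
  long <- rbindlist(lapply(ids, function(id) {
    tab <- samples$tables[[id]]
    keep_site <- tab$context == context     # plain vector: avoids i-scope capture
    tab <- tab[keep_site, c("chrom", "pos", "strand", "m", "n")]
    tab$sample_id <- id
    tab
  }))
  if (nrow(long) == 0L)
    return(data.table(chrom = character(), pos = integer(), strand = character(),
                      context = character()))
  wide <- dcast(long, chrom + pos + strand ~ sample_id,
                value.var = c("m", "n"), fill = 0L, sep = ".")
  # dcast orders value columns m.<id>..., n.<id>...; keep sample order
  setcolorder(wide, c("chrom", "pos", "strand",
                      paste0("m.", ids), paste0("n.", ids)))
  wide[, context := context]
  setorder(wide, chrom, pos, strand)
  wide[]
}

#' Call differentially methylated cytosines (DMCs)
#'
#' Tests every site of one context class whose coverage satisfies
#' `cov_min` (per sample by default), using the RMS statistic and its
#' margin-fixed permutation null, then applies Benjamini-Hochberg across
#' all tested sites in one genome-wide batch. A site is a DMC when
#' q <= `fdr`.
#'
#' @param samples a [sample_set()]; replicates should already be pooled
#'   (see [pool_replicates()]).
#' @param context context class to test.
#' @param fdr BH false-discovery-rate threshold (default 0.01).
#' @param cov_min minimum reads per site (default 4).
#' @param cov_rule `"per_sample"` (every sample must reach `cov_min`) or
#'   `"pooled"` (summed coverage must).
#' @param P Monte-Carlo permutations for sites where exact enumeration is
#'   infeasible.
#' @param seed integer seed for Monte-Carlo draws.
#' @param exact_limit see [permutation_pvalue()].
#' @return data.table of tested sites: chrom, pos, strand, context,
#'   per-sample m/n, rms, p, q, is_dmc and per-sample direction columns
#'   `dir.<id>` (sign of sample proportion minus pooled proportion).
#' @export
call_dmcs <- function(samples, context, fdr = 0.01, cov_min = 4L,
                      cov_rule = c("per_sample", "pooled"),
                      P = 1000L, seed = 1L, exact_limit = 1e5) {
  cov_rule <- match.arg(cov_rule)
  ids <- names(samples$tables)
  sites <- build_site_table(samples, context)
  if (nrow(sites) == 0L) {
    warning("no sites of context ", context)
    return(sites)
  }
  mcols <- paste0("m.", ids)
  ncols <- paste0("n.", ids)
  nm <- as.matrix(sites[, ..ncols])
  keep <- if (cov_rule == "per_sample") rowSums(nm >= cov_min) == length(ids)
          else rowSums(nm) >= cov_min
  sites <- sites[keep, ]
  if (nrow(sites) == 0L) {
    warning("no testable sites of context ", context, " at cov_min ", cov_min)
    return(sites)
  }
  mm <- as.matrix(sites[, ..mcols])
  nm <- as.matrix(sites[, ..ncols])
  N <- rowSums(nm); M <- rowSums(mm); S <- length(ids)
  e1 <- nm * (M / N)
  sites[, rms := sqrt(rowSums(((mm - e1) / N)^2) * 2 / (2 * S))]
  if (S == 2L) {
    sites[, p := exact_pvalue_two_sample(mm[, 1L], nm[, 1L], mm[, 2L], nm[, 2L])]
  } else {
    set.seed(seed)
    sites[, p := vapply(seq_len(.N), function(i)
      as.numeric(permutation_pvalue(mm[i, ], nm[i, ], P = P,
                                    exact_limit = exact_limit)),
      numeric(1L))]
  }
  sites[, q := p.adjust(p, method = "BH")]
  sites[, is_dmc := q <= fdr]
  dirs <- sign(mm / pmax(nm, 1L) - M / N)
  colnames(dirs) <- paste0("dir.", ids)
  cbind(sites, as.data.table(dirs))[]
}

#' Pool replicate cytosine tables by summing counts
#'
#' Biological replicates of one tissue/condition are pooled (counts summed
#' site-wise) before differential testing.
#'
#' @param samples a [sample_set()].
#' @param groups named list mapping pooled-sample id to the replicate ids
#'   to sum.
#' @return a new [sample_set()] with one table per group.
#' @export
pool_replicates <- function(samples, groups) {
  tabs <- lapply(groups, function(ids) {
    stopifnot(all(ids %in% names(samples$tables)))
    long <- rbindlist(samples$tables[ids])
    pooled <- long[, .(m = sum(m), n = sum(n)), by = .(chrom, pos, strand, context)]
    cytosine_table(pooled$chrom, pooled$pos, pooled$strand, pooled$context,
                   pooled$m, pooled$n)
  })
  sample_set(tabs)
}

#' Collapse DMCs into differentially methylated regions (DMRs)
#'
#' Chains of DMCs in which consecutive members lie within `window` bp
#' become candidate units; units with at least `min_dmcs` members (default
#' 8 for CG, 4 for non-CG) become DMRs spanning first to last member DMC
#' (half-open end = last position + 1). Per-sample weighted methylation
#' over member DMCs is reported when per-sample counts are present.
#'
#' @param dmcs output of [call_dmcs()]; only rows with `is_dmc` are used
#'   (pass any site table plus `already_filtered = TRUE` to skip that).
#' @param context_class `"CG"` or `"nonCG"` (sets the `min_dmcs` default).
#' @param window maximum spacing between consecutive DMCs in one unit (bp).
#' @param min_dmcs minimum DMCs per DMR; default 8 (CG) / 4 (nonCG).
#' @param already_filtered treat every input row as a DMC.
#' @return a [region_set()] of kind "DMR" with `n_dmcs` and per-sample
#'   rate columns; attribute `context_class`.
#' @export
collapse_dmrs <- function(dmcs, context_class = c("CG", "nonCG"),
                          window = 500L, min_dmcs = NULL,
                          already_filtered = FALSE) {
  context_class <- match.arg(context_class)
  if (is.null(min_dmcs)) min_dmcs <- if (context_class == "CG") 8L else 4L
  dt <- as.data.table(dmcs)
  if (!already_filtered && "is_dmc" %in% names(dt)) dt <- dt[is_dmc == TRUE]
  empty <- {
    rs <- region_set()
    setattr(rs, "context_class", context_class)
    rs
  }
  if (nrow(dt) == 0L) return(empty)
  setorder(dt, chrom, pos)
  dt[, unit := cumsum(c(1L, (diff(pos) > window) | (chrom[-1L] != chrom[-.N])))]
  mcols <- grep("^m\\.", names(dt), value = TRUE)
  ncols <- grep("^n\\.", names(dt), value = TRUE)
  agg <- dt[, c(.(chrom = chrom[1L], start = min(pos), end = max(pos) + 1L,
                  n_dmcs = .N),
                lapply(.SD, sum)),
            by = unit, .SDcols = c(mcols, ncols)]
  agg <- agg[n_dmcs >= min_dmcs]
  if (nrow(agg) == 0L) return(empty)
  out <- region_set(chrom = agg$chrom, start = agg$start, end = agg$end,
                    strand = ".", label = sprintf("DMR_%s_%s_%d", context_class,
                                                  agg$chrom, agg$start),
                    kind = "DMR", n_dmcs = agg$n_dmcs)
  for (mc in mcols) {
    id <- sub("^m\\.", "", mc)
    key <- match(paste(out$chrom, out$start), paste(agg$chrom, agg$start))
    out[, (paste0("rate.", id)) := agg[[mc]][key] / pmax(agg[[sub("^m", "n", mc)]][key], 1L)]
  }
  setattr(out, "context_class", context_class)
  out[]
}

#' Union-merge several DMR sets into one
#'
#' Overlapping or book-ended intervals across the input sets are merged.
#' All inputs must share one context class. Merged DMRs carry the summed
#' `n_dmcs` of their members and should be re-scored across samples with
#' [methylation_matrix()].
#'
#' @param sets list of DMR [region_set()]s with matching `context_class`.
#' @return merged [region_set()] of kind "DMR".
#' @export
merge_dmr_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s) > 0L, sets)
  if (length(sets) == 0L) return(region_set())
  cls <- unique(vapply(sets, function(s)
    attr(s, "context_class") %||% NA_character_, character(1L)))
  cls <- cls[!is.na(cls)]
  if (length(cls) > 1L) stop("mixed context classes: ", paste(cls, collapse = ", "))
  all <- rbindlist(sets, fill = TRUE)
  gr <- GenomicRanges::reduce(regions_to_gr(all), ignore.strand = TRUE)
  out <- gr_to_regions(gr, kind = "DMR")
  out[, label := sprintf("DMR_%s_%d", chrom, start)]
  if ("n_dmcs" %in% names(all)) {
    hits <- GenomicRanges::findOverlaps(regions_to_gr(all), gr, ignore.strand = TRUE)
    nd <- data.table(j = S4Vectors::subjectHits(hits),
                     n = all$n_dmcs[S4Vectors::queryHits(hits)])[, .(n = sum(n)), by = j]
    out[, n_dmcs := 0L][nd$j, n_dmcs := nd$n]
  }
  if (length(cls) == 1L) setattr(out, "context_class", cls)
  out[]
}

#' Overlap summary between two DMR sets
#'
#' Union-merges each side, intersects, and counts merged overlap events.
#' The percentage is of the combined set sizes (nA + nB) by default —
#' matching the convention in which 183 overlaps out of 1185 + 1398 DMRs
#' print as 7.1% — or of the union-merged total.
#'
#' @param setA,setB DMR [region_set()]s.
#' @param denominator `"total"` (nA + nB) or `"union"`.
#' @return list: nA, nB, n_overlap, pct_of_total (1 decimal).
#' @export
overlap_summary <- function(setA, setB, denominator = c("total", "union")) {
  denominator <- match.arg(denominator)
  if (nrow(setA) == 0L || nrow(setB) == 0L)
    return(list(nA = nrow(setA), nB = nrow(setB), n_overlap = 0L, pct_of_total = 0))
  grA <- GenomicRanges::reduce(regions_to_gr(setA), ignore.strand = TRUE)
  grB <- GenomicRanges::reduce(regions_to_gr(setB), ignore.strand = TRUE)
  ov <- GenomicRanges::reduce(GenomicRanges::intersect(grA, grB, ignore.strand = TRUE))
  nA <- length(grA); nB <- length(grB); n_ov <- length(ov)
  den <- if (denominator == "total") nA + nB
         else length(GenomicRanges::reduce(c(grA, grB)))
  list(nA = nA, nB = nB, n_overlap = n_ov,
       pct_of_total = round(100 * n_ov / den, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
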