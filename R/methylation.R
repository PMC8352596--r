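# Weighted methylation = sum(m)/sum(n) over the cytosines of one context in
# a region; the coverage-weighted rate used throughout.

# Per-region pooled counts for one context. Returns data.table aligned with
# `regions` rows: m_sum, n_sum, informative_sites (sites with n >= cov_min).
region_counts <- function(table, regions, context, cov_min = 1L) {
  stopifnot(cov_min >= 1L)
  res <- data.table(m_sum = integer(nrow(regions)), n_sum = integer(nrow(regions)),
                    informative_sites = integer(nrow(regions)))
  keep_site <- table$context == context & table$n >= cov_min
  sites <- table[keep_site, ]
  if (nrow(sites) == 0L || nrow(regions) == 0L) return(res)
  hits <- suppressWarnings(          # disjoint chromosome sets are legitimate
    GenomicRanges::findOverlaps(sites_to_gr(sites), regions_to_gr(regions),
                                ignore.strand = TRUE))
  if (length(hits) == 0L) return(res)
  dt <- data.table(ri = S4Vectors::subjectHits(hits),
                   m = sites$m[S4Vectors::queryHits(hits)],
                   n = sites$n[S4Vectors::queryHits(hits)])
  agg <- dt[, .(m_sum = sum(m), n_sum = sum(n), informative_sites = .N), by = ri]
  res[agg$ri, `:=`(m_sum = agg$m_sum, n_sum = agg$n_sum,
                   informative_sites = agg$informative_sites)]
  res
}

#' Weighted methylation of a region
#'
#' Pools methylated/total read counts over all cytosines of `context`
#' inside `region` with coverage `n >= cov_min` and returns the weighted
#' rate sum(m)/sum(n). When fewer than `min_sites` informative cytosines are
#' covered (or no reads at all), the rate is undefined (`NA`), never 0.
#'
#' @param table a [cytosine_table()].
#' @param region a single-row [region_set()] (or any 1-row data.frame with
#'   chrom/start/end).
#' @param context "CG", "CHG" or "CHH".
#' @param cov_min minimum reads for a cytosine to count as informative.
#' @param min_sites minimum informative cytosines for a defined rate.
#' @return list with `rate`, `m_sum`, `n_sum`, `informative_sites`.
#' @export
weighted_methylation <- function(table, region, context,
                                 cov_min = 1L, min_sites = 0L) {
  stopifnot(nrow(region) == 1L)
  rc <- region_counts(table, region, context, cov_min)
  rate <- if (rc$n_sum > 0L && rc$informative_sites >= min_sites)
    rc$m_sum / rc$n_sum else NA_real_
  list(rate = rate, m_sum = rc$m_sum, n_sum = rc$n_sum,
       informative_sites = rc$informative_sites)
}

#' Weighted methylation for every region of a set
#'
#' Vectorised form of [weighted_methylation()]; one row per region.
#'
#' @inheritParams weighted_methylation
#' @param regions a [region_set()].
#' @return data.table: label, context, m_sum, n_sum, rate, informative_sites.
#' @export
region_methylation <- function(table, regions, context,
                               cov_min = 1L, min_sites = 0L) {
  rc <- region_counts(table, regions, context, cov_min)
  rate <- ifelse(rc$n_sum > 0L & rc$informative_sites >= min_sites,
                 rc$m_sum / rc$n_sum, NA_real_)
  data.table(label = regions$label, context = context,
             m_sum = rc$m_sum, n_sum = rc$n_sum, rate = rate,
             informative_sites = rc$informative_sites)
}

#' Filter regions by cytosine coverage
#'
#' Two printed filters are in use for different analyses and both are
#' expressible here: the TE filter keeps regions with at least `min_sites`
#' cytosines covered by `cov_min` or more reads (`mode = "sites"`, defaults
#' 4 reads / 5 sites); the genic filter keeps regions whose pooled read
#' count over context sites reaches `min_reads` (`mode = "reads"`).
#'
#' @inheritParams region_methylation
#' @param mode `"sites"` (informative-site rule) or `"reads"` (pooled-read
#'   rule).
#' @param min_reads pooled-read threshold for `mode = "reads"`.
#' @return the passing subset of `regions` (a [region_set()]).
#' @export
filter_regions_by_coverage <- function(table, regions, context,
                                       cov_min = 4L, min_sites = 5L,
                                       mode = c("sites", "reads"),
                                       min_reads = 5L) {
  mode <- match.arg(mode)
  if (nrow(regions) == 0L) return(regions)
  if (mode == "sites") {
    rc <- region_counts(table, regions, context, cov_min)
    keep <- rc$informative_sites >= min_sites
  } else {
    rc <- region_counts(table, regions, context, cov_min = 1L)
    keep <- rc$n_sum >= min_reads
  }
  regions[keep, ]
}

#' Bisulfite conversion rate from an unmethylated control chromosome
#'
#' The chloroplast genome is unmethylated, so any methylated calls on it
#' measure conversion failure: rate = 1 - sum(m)/sum(n) over all contexts.
#'
#' @param table a [cytosine_table()].
#' @param control_chrom control chromosome name (exact match).
#' @return conversion rate in [0, 1].
#' @export
conversion_rate <- function(table, control_chrom) {
  ctl <- table[table$chrom == control_chrom, ]
  if (nrow(ctl) == 0L) stop("control chromosome not present: ", control_chrom)
  n_sum <- sum(ctl$n)
  if (n_sum == 0L) stop("control chromosome has no read coverage: ", control_chrom)
  1 - sum(ctl$m) / n_sum
}

#' Region-by-sample matrix of weighted methylation rates
#'
#' @param samples a [sample_set()].
#' @inheritParams region_methylation
#' @return numeric matrix (regions x samples), `NA` where the coverage rule
#'   fails; rownames are region labels.
#' @export
methylation_matrix <- function(samples, regions, context,
                               cov_min = 1L, min_sites = 0L) {
  cols <- lapply(samples$tables, function(tab)
    region_methylation(tab, regions, context, cov_min, min_sites)$rate)
  mat <- do.call(cbind, cols)
  rownames(mat) <- regions$label
  colnames(mat) <- names(samples$tables)
  mat
}
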