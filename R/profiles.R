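# Metagene ("metaplot") machinery: regions are rescaled to a fixed
# flank-body-flank bin grid, oriented 5'->3', and weighted methylation is
# computed per bin.

# Per-region, per-bin weighted methylation. Returns a regions x bins matrix
# (NA where a bin has no covered site); attribute "skipped" counts regions
# shorter than n_body bp, which are excluded.
region_bin_rates <- function(table, regions, context,
                             n_up = 10L, n_body = 20L, n_down = 10L,
                             flank_bp = 1500L, cov_min = 1L) {
  B <- n_up + n_body + n_down
  len <- regions$end - regions$start
  keep <- len >= n_body
  skipped <- sum(!keep)
  regions <- regions[keep, ]
  if (nrow(regions) == 0L)
    return(structure(matrix(numeric(0), 0L, B), skipped = skipped))
  keep_site <- table$context == context & table$n >= cov_min
  sites <- table[keep_site, ]
  mat_m <- matrix(0L, nrow(regions), B)
  mat_n <- matrix(0L, nrow(regions), B)
  if (nrow(sites) > 0L) {
    ext <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(start = pmax(regions$start - flank_bp, 0L) + 1L,
                       end = regions$end + flank_bp))
    hits <- GenomicRanges::findOverlaps(sites_to_gr(sites), ext,
                                        ignore.strand = TRUE)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits)
      ri <- S4Vectors::subjectHits(hits)
      off <- sites$pos[qi] - regions$start[ri]
      rl <- (regions$end - regions$start)[ri]
      bin <- integer(length(off))
      up <- off < 0L
      body <- off >= 0L & off < rl
      down <- off >= rl
      bin[up] <- pmax(0L, floor((off[up] + flank_bp) * n_up / flank_bp))
      bin[body] <- n_up + pmin(n_body - 1L, floor(off[body] * n_body / rl[body]))
      bin[down] <- n_up + n_body +
        pmin(n_down - 1L, floor((off[down] - rl[down]) * n_down / flank_bp))
      ok <- bin >= 0L & bin < B
      qi <- qi[ok]; ri <- ri[ok]; bin <- bin[ok]
      minus <- regions$strand[ri] == "-"
      bin[minus] <- B - 1L - bin[minus]
      idx <- (bin) * nrow(regions) + ri        # column-major cell index
      dt <- data.table(idx = idx, m = sites$m[qi], n = sites$n[qi])
      agg <- dt[, .(m = sum(m), n = sum(n)), by = idx]
      mat_m[agg$idx] <- agg$m
      mat_n[agg$idx] <- agg$n
    }
  }
  rates <- ifelse(mat_n > 0L, mat_m / mat_n, NA_real_)
  rates <- matrix(rates, nrow(regions), B)
  rownames(rates) <- regions$label
  structure(rates, skipped = skipped)
}

#' Metagene profile of weighted methylation across a region set
#'
#' Each region is oriented 5'->3' (minus-strand regions are reversed) and
#' rescaled to `n_up` fixed-width upstream bins over `flank_bp` bp,
#' `n_body` fractional body bins and `n_down` downstream bins. Per-bin
#' weighted methylation is computed per region; the profile is the
#' cross-region mean per bin, ignoring undefined cells. Regions shorter
#' than `n_body` bp are skipped (their count is reported).
#'
#' @inheritParams region_methylation
#' @param n_up,n_body,n_down bin counts (defaults 10/20/10).
#' @param flank_bp flank width in bp (default 1500).
#' @return list of class `meta_profile`: `values` (per-bin mean),
#'   `spread` (per-bin sd), `n_regions`, `n_skipped`, bin layout.
#' @export
metaprofile <- function(table, regions, context, n_up = 10L, n_body = 20L,
                        n_down = 10L, flank_bp = 1500L, cov_min = 1L) {
  rates <- region_bin_rates(table, regions, context, n_up, n_body, n_down,
                            flank_bp, cov_min)
  if (nrow(rates) == 0L)
    stop("all regions skipped (shorter than n_body = ", n_body, " bp)")
  structure(list(values = colMeans(rates, na.rm = TRUE),
                 spread = apply(rates, 2L, sd, na.rm = TRUE),
                 n_regions = nrow(rates),
                 n_skipped = attr(rates, "skipped"),
                 n_up = n_up, n_body = n_body, n_down = n_down,
                 flank_bp = flank_bp),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", x$n_up, "+", x$n_body, "+", x$n_down, "bins,",
      x$n_regions, "regions (", x$n_skipped, "skipped )\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Per-gene binned methylation-difference profiles
#'
#' For every gene passing the coverage filter, computes per-bin weighted
#' methylation in `tableA` and `tableB` and returns the difference
#' (A - B), e.g. mutant minus wild type. Undefined bins are imputed as 0
#' difference so the rows are complete for clustering; the per-row count
#' of imputed bins is kept in attribute `"n_imputed"`.
#'
#' @param tableA,tableB [cytosine_table()]s for the two conditions.
#' @param genes gene [region_set()] (stranded).
#' @param context context class (typically "CHG").
#' @param n_up,n_body,n_down,flank_bp bin layout as in [metaprofile()].
#' @param cov_min per-site coverage floor within bins.
#' @param min_reads genes are kept when pooled reads over context sites in
#'   `tableA` reach this (the expressed-gene coverage rule); set 0 to skip.
#' @return genes x bins numeric matrix (rownames = gene labels) with
#'   attributes `n_imputed` (per-row) and `layout`.
#' @export
difference_profiles <- function(tableA, tableB, genes, context = "CHG",
                                n_up = 10L, n_body = 20L, n_down = 10L,
                                flank_bp = 1500L, cov_min = 1L,
                                min_reads = 5L) {
  if (min_reads > 0L)
    genes <- filter_regions_by_coverage(tableA, genes, context,
                                        mode = "reads", min_reads = min_reads)
  if (nrow(genes) == 0L) stop("no genes pass the coverage filter")
  rA <- region_bin_rates(tableA, genes, context, n_up, n_body, n_down,
                         flank_bp, cov_min)
  rB <- region_bin_rates(tableB, genes, context, n_up, n_body, n_down,
                         flank_bp, cov_min)
  diff <- rA - rB
  n_imp <- rowSums(is.na(diff))
  diff[is.na(diff)] <- 0
  attr(diff, "skipped") <- NULL
  structure(diff, n_imputed = n_imp,
            layout = c(n_up = n_up, n_body = n_body, n_down = n_down))
}

#' Centromere-distance percentile summary of methylation differences
#'
#' Tiles the genome into `bin_bp` windows, computes the per-bin weighted
#' methylation difference (A - B) for `context`, ranks covered bins by the
#' distance from bin midpoint to the nearest centromere midpoint, and
#' splits them into 100 equal-count percentiles (1 = closest). Ties in
#' distance are broken by (chrom, start) so the assignment is
#' deterministic.
#'
#' @inheritParams difference_profiles
#' @param bin_bp genomic bin width (default 1000).
#' @param centromeres data.frame with columns `chrom`, `mid` (centromere
#'   midpoint, 0-based bp).
#' @param genome_sizes named numeric vector of chromosome lengths; control
#'   or unlisted chromosomes are ignored.
#' @return data.table: percentile, n_bins, median, q25, q75, lo, hi
#'   (whiskers at 1.5 x IQR, clamped to the data range).
#' @export
centromere_percentiles <- function(tableA, tableB, context = "CG",
                                   bin_bp = 1000L, centromeres = NULL,
                                   genome_sizes = NULL) {
  stopifnot(!is.null(centromeres), !is.null(genome_sizes))
  chroms <- intersect(names(genome_sizes), unique(centromeres$chrom))
  if (length(chroms) == 0L) stop("no chromosomes shared with centromere table")
  bins <- rbindlist(lapply(chroms, function(ch) {
    starts <- seq(0L, genome_sizes[[ch]] - 1L, by = bin_bp)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + bin_bp, as.integer(genome_sizes[[ch]])))
  }))
  breg <- region_set(chrom = bins$chrom, start = bins$start, end = bins$end,
                     kind = "bin")
  rA <- region_methylation(tableA, breg, context)
  rB <- region_methylation(tableB, breg, context)
  dt <- data.table(chrom = breg$chrom, start = breg$start, end = breg$end,
                   diff = rA$rate - rB$rate)
  dt <- dt[!is.na(diff)]
  if (nrow(dt) < 100L)
    stop("only ", nrow(dt), " covered bins; need >= 100 (try larger bin_bp)")
  cen <- setNames(centromeres$mid, centromeres$chrom)
  dt[, dist := abs((start + end) / 2 - cen[chrom])]
  setorder(dt, dist, chrom, start)
  dt[, percentile := floor((seq_len(.N) - 1L) * 100L / .N) + 1L]
  dt[, .(n_bins = .N,
         median = median(diff),
         q25 = quantile(diff, 0.25, names = FALSE),
         q75 = quantile(diff, 0.75, names = FALSE),
         lo = max(min(diff), quantile(diff, 0.25, names = FALSE) -
                    1.5 * IQR(diff)),
         hi = min(max(diff), quantile(diff, 0.75, names = FALSE) +
                    1.5 * IQR(diff))),
     by = percentile][order(percentile)]
}
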