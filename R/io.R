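#' Read a per-cytosine methylation call table
#'
#' Supports the two common caller outputs:
#' \describe{
#'   \item{`allc`}{methylpy-style TSV: chrom, 1-based position, strand,
#'     trinucleotide context, methylated reads, total reads, optional
#'     binary call column.}
#'   \item{`cx_report`}{Bismark cytosine report: chrom, 1-based position,
#'     strand, methylated count, unmethylated count, context class,
#'     trinucleotide.}
#' }
#' Positions are converted to the internal 0-based convention and contexts
#' collapsed to {CG, CHG, CHH}. Zero-coverage rows are retained (coverage
#' filters act downstream).
#'
#' @param path TSV file path.
#' @param format `"allc"` or `"cx_report"`.
#' @return A [cytosine_table()].
#' @export
read_cytosine_table <- function(path, format = c("allc", "cx_report")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty cytosine table: ", path)
    return(cytosine_table())
  }
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE, data.table = TRUE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  ncol_need <- if (format == "allc") 6L else 7L
  if (ncol(dt) < ncol_need)
    stop("parse error in ", path, ": expected >= ", ncol_need, " columns, got ", ncol(dt))
  if (format == "allc") {
    out <- dt[, .(chrom = as.character(V1), pos1 = V2, strand = as.character(V3),
                  context = as.character(V4), m = V5, n = V6)]
  } else {
    out <- dt[, .(chrom = as.character(V1), pos1 = V2, strand = as.character(V3),
                  context = as.character(V7), m = V4, n = V4 + V5)]
  }
  bad <- which(is.na(out$pos1) | is.na(out$m) | is.na(out$n))
  if (length(bad)) stop("malformed line ", bad[1L], " in ", path)
  over <- which(out$m > out$n)
  if (length(over)) stop("validation error in ", path, ": m > n at line ", over[1L])
  cytosine_table(chrom = out$chrom, pos = out$pos1 - 1L, strand = out$strand,
                 context = out$context, m = out$m, n = out$n)
}

#' Write a cytosine table as allc-style TSV (1-based positions)
#'
#' @param table a [cytosine_table()].
#' @param path output path.
#' @return `path`, invisibly. Round-trips through [read_cytosine_table()].
#' @export
write_cytosine_table <- function(table, path) {
  out <- data.table(table$chrom, table$pos + 1L, table$strand,
                    table$context, table$m, table$n)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read genomic regions from BED or a minimal GFF-like TSV
#'
#' BED input is 0-based half-open; `gff_lite` (chrom, source, feature,
#' start, end, score, strand, frame, attribute/label — or the 5-column
#' chrom, start, end, strand, label variant) is 1-based inclusive and is
#' converted. All regions are stored 0-based half-open.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff_lite"`.
#' @param kind region kind recorded on every row.
#' @return A [region_set()].
#' @export
read_regions <- function(path, format = c("bed", "gff_lite"), kind = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty region file: ", path)
    return(region_set())
  }
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE, data.table = TRUE)
  if (format == "bed") {
    if (ncol(dt) < 3L) stop("BED needs >= 3 columns: ", path)
    start <- dt$V2; end <- dt$V3
    label <- if (ncol(dt) >= 4L) as.character(dt$V4) else NA_character_
    strand <- if (ncol(dt) >= 6L) as.character(dt$V6) else "."
  } else {
    if (ncol(dt) >= 9L) {        # GFF-shaped
      start <- dt$V4 - 1L; end <- dt$V5
      strand <- as.character(dt$V7)
      label <- as.character(dt$V9)
    } else if (ncol(dt) >= 5L) { # chrom start end strand label, 1-based inclusive
      start <- dt$V2 - 1L; end <- dt$V3
      strand <- as.character(dt$V4)
      label <- as.character(dt$V5)
    } else stop("gff_lite needs >= 5 columns: ", path)
  }
  bad <- which(start >= end)
  if (length(bad))
    stop("validation error in ", path, ": start >= end after conversion at line ", bad[1L])
  region_set(chrom = as.character(dt$V1), start = start, end = end,
             strand = ifelse(strand %in% c("+", "-"), strand, "."),
             label = label, kind = kind)
}

#' Write regions as BED6, sorted by (chrom, start)
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly. Round-trips through [read_regions()].
#' @export
write_regions <- function(regions, path) {
  validate_region_set(regions)
  out <- as.data.table(regions)[order(chrom, start, end),
                                .(chrom, start, end, label, score = 0L, strand)]
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot write ", path))
  close(con)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
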