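#' @import data.table
#' @importFrom stats median p.adjust quantile sd cor.test fisher.test IQR
#'   phyper dhyper rhyper kmeans rbinom rpois runif rnorm setNames complete.cases
#' @importFrom utils head
#' @importFrom yaml read_yaml
NULL

CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a per-cytosine methylation call table
#'
#' The table is the package's central per-sample container: one row per
#' cytosine with methylated (`m`) and total (`n`) read counts and the
#' trinucleotide context collapsed to its class (CG/CHG/CHH). All positions
#' are stored 0-based; 1-based inputs are converted exactly once, on
#' ingestion.
#'
#' @param chrom character chromosome names.
#' @param pos integer 0-based cytosine positions.
#' @param strand "+" or "-".
#' @param context context class or raw trinucleotide (collapsed via
#'   [context_class()]).
#' @param m,n methylated and total read counts; `m <= n` required.
#' @return A `cytosine_table` (also a `data.table`), sorted by
#'   (chrom, pos, strand).
#' @export
cytosine_table <- function(chrom = character(), pos = integer(),
                           strand = character(), context = character(),
                           m = integer(), n = integer()) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand),
                   context = context_class(as.character(context)),
                   m = as.integer(m), n = as.integer(n))
  validate_cytosine_table(dt)
  setorder(dt, chrom, pos, strand)
  setattr(dt, "class", c("cytosine_table", class(dt)))
  dt[]
}

validate_cytosine_table <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(dt$pos < 0L)) stop("cytosine positions must be >= 0 (0-based)")
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  bad <- which(!(dt$context %in% CONTEXTS))
  if (length(bad)) stop("unknown context at row ", bad[1L], ": ", dt$context[bad[1L]])
  if (any(dt$m < 0L) || any(dt$n < 0L)) stop("counts must be non-negative")
  over <- which(dt$m > dt$n)
  if (length(over)) stop("m > n at row ", over[1L],
                         " (m=", dt$m[over[1L]], ", n=", dt$n[over[1L]], ")")
  invisible(dt)
}

#' Collapse a trinucleotide to its methylation context class
#'
#' `CGN -> CG`; `CHG` with H in {A,C,T} stays CHG; everything else with a
#' non-G second base is CHH. Already-collapsed labels pass through.
#'
#' @param tri character vector of trinucleotides or context labels.
#' @return character vector over {CG, CHG, CHH}.
#' @export
context_class <- function(tri) {
  tri <- toupper(tri)
  out <- tri
  raw <- !(tri %in% CONTEXTS)
  if (any(raw)) {
    t2 <- substr(tri[raw], 2L, 2L)
    t3 <- substr(tri[raw], 3L, 3L)
    cls <- ifelse(t2 == "G", "CG", ifelse(t3 == "G", "CHG", "CHH"))
    bad <- !grepl("^C[ACGTN]{2}$", tri[raw])
    if (any(bad)) stop("cannot classify context: ", tri[raw][bad][1L])
    out[raw] <- cls
  }
  out
}

#' Construct a genomic region set
#'
#' Plain-data container for genes, TEs, DMRs or bins. Coordinates are
#' 0-based half-open (`start < end`) regardless of the input dialect.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param strand "+", "-" or "." (unstranded).
#' @param label region identifier.
#' @param kind one of gene, TE, DMR, bin, other.
#' @param ... further per-region columns (e.g. `n_dmcs`).
#' @return A `region_set` (also a `data.table`) sorted by (chrom, start).
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       strand = ".", label = NA_character_, kind = "other", ...) {
  nr <- max(length(chrom), length(start), length(end))
  dt <- data.table(chrom = rep_len(as.character(chrom), nr),
                   start = rep_len(as.integer(start), nr),
                   end = rep_len(as.integer(end), nr),
                   strand = rep_len(as.character(strand), nr),
                   label = rep_len(as.character(label), nr),
                   kind = rep_len(as.character(kind), nr), ...)
  if (nr > 0L && any(is.na(dt$label))) {
    idx <- which(is.na(dt$label))
    dt[idx, label := paste0("region_", .I)]
  }
  validate_region_set(dt)
  setorder(dt, chrom, start, end)
  setattr(dt, "class", c("region_set", class(dt)))
  dt[]
}

validate_region_set <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(dt$start < 0L)) stop("negative interval start")
  bad <- which(dt$start >= dt$end)
  if (length(bad)) stop("start >= end at row ", bad[1L], " (",
                        dt$chrom[bad[1L]], ":", dt$start[bad[1L]], "-", dt$end[bad[1L]], ")")
  if (!all(dt$strand %in% c("+", "-", "."))) stop("strand must be '+', '-' or '.'")
  invisible(dt)
}

#' Bundle per-sample cytosine tables into an ordered sample set
#'
#' @param tables named list of `cytosine_table`s (names are sample ids).
#' @param stage optional per-sample tissue/stage labels.
#' @param genotype optional per-sample genotype labels.
#' @return A `sample_set` list with elements `tables`, `info`.
#' @export
sample_set <- function(tables, stage = NULL, genotype = NULL) {
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stop("tables must be a named list with unique sample ids")
  info <- data.table(sample_id = names(tables),
                     stage = rep_len(if (is.null(stage)) NA_character_ else stage, length(tables)),
                     genotype = rep_len(if (is.null(genotype)) NA_character_ else genotype, length(tables)))
  structure(list(tables = tables, info = info), class = "sample_set")
}

# region_set -> GRanges (internal; 0-based half-open -> 1-based closed)
regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = ifelse(regions$strand %in% c("+", "-"), regions$strand, "*"))
}

gr_to_regions <- function(gr, kind = "other", label = NULL) {
  st <- as.character(GenomicRanges::strand(gr))
  region_set(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = ifelse(st == "*", ".", st),
             label = if (is.null(label)) NA_character_ else label,
             kind = kind)
}

sites_to_gr <- function(table) {
  GenomicRanges::GRanges(seqnames = table$chrom,
                         ranges = IRanges::IRanges(start = table$pos + 1L, width = 1L))
}
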