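# DMR-gene association within flanking windows and overlap-enrichment
# statistics (gene-level hypergeometric as the primary test; a base-pair
# interval variant kept for fidelity to genome-background Fisher testing).

#' Associate DMRs with genes within a flanking window
#'
#' A gene and a DMR are linked when the DMR intersects
#' [gene.start - flank, gene.end + flank). The relation is classified
#' strand-aware: `overlaps_body` when the DMR touches the gene body,
#' otherwise `upstream` / `downstream` of the 5' / 3' end with the gap
#' distance in bp. A gene may link many DMRs and vice versa.
#'
#' @param dmrs DMR [region_set()].
#' @param genes gene [region_set()] (stranded).
#' @param flank window size in bp (default 1500).
#' @return data.table: gene, dmr, relation, distance.
#' @export
associate_dmrs_genes <- function(dmrs, genes, flank = 1500L) {
  empty <- data.table(gene = character(), dmr = character(),
                      relation = character(), distance = integer())
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(empty)
  # widen by flank+1 so book-ended candidates at gap == flank are seen by
  # the overlap query; the gap filter below imposes the exact rule
  ext <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - flank - 1L, 0L) + 1L,
                     end = genes$end + flank + 1L))
  hits <- GenomicRanges::findOverlaps(regions_to_gr(dmrs), ext,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  di <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ds <- dmrs$start[di]; de <- dmrs$end[di]
  gs <- genes$start[gi]; ge <- genes$end[gi]
  overlaps <- ds < ge & de > gs
  left <- de <= gs                 # DMR entirely on the lower-coordinate side
  gap <- ifelse(overlaps, 0L, ifelse(left, gs - de, ds - ge))
  minus <- genes$strand[gi] == "-"
  relation <- ifelse(overlaps, "overlaps_body",
                     ifelse(left != minus, "upstream", "downstream"))
  data.table(gene = genes$label[gi], dmr = dmrs$label[di],
             relation = relation, distance = as.integer(gap))[distance <= flank]
}

#' Gene-set overlap enrichment (hypergeometric / Fisher)
#'
#' Tests whether the overlap of two gene sets within a stated universe is
#' larger than chance: one-sided hypergeometric tail P(X >= |A & B|) with
#' N = |universe|, K = |B|, n = |A|, plus the two-sided Fisher p on the
#' 2 x 2 table.
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector defining the background.
#' @param two_sided also compute the two-sided Fisher p (default TRUE;
#'   disable when only the hypergeometric tail is needed in bulk).
#' @return list of class `enrichment_result`: counts a (A&B), b (A only),
#'   c (B only), d (neither), `odds_ratio`, `p_one_sided`, `p_two_sided`,
#'   `universe_n`.
#' @export
gene_set_overlap_test <- function(setA, setB, universe, two_sided = TRUE) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  outA <- setdiff(setA, universe); outB <- setdiff(setB, universe)
  if (length(outA) || length(outB))
    stop("sets not subsets of universe: ",
         paste(head(c(outA, outB), 5L), collapse = ", "))
  N <- length(universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  cc <- length(setB) - a
  d <- N - a - b - cc
  p1 <- phyper(a - 1L, length(setB), N - length(setB), length(setA),
               lower.tail = FALSE)
  ft <- if (two_sided) fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
  structure(list(a = a, b = b, c = cc, d = d,
                 odds_ratio = if (b * cc == 0) NA_real_ else (a * d) / (b * cc),
                 odds_ratio_mle = if (two_sided) unname(ft$estimate) else NA_real_,
                 p_one_sided = p1,
                 p_two_sided = if (two_sided) ft$p.value else NA_real_,
                 universe_n = N),
            class = "enrichment_result")
}

#' Base-pair interval overlap enrichment against a genome background
#'
#' Union-merges each side, partitions the genome into base-pair units that
#' are query-only, reference-only, both, or neither, and applies Fisher's
#' exact test to that 2 x 2 table. This treats base pairs as exchangeable
#' units and is an approximation to interval-overlap significance (the
#' convention of genome-background interval Fisher tests).
#'
#' @param query,reference [region_set()]s.
#' @param genome_sizes named vector of chromosome lengths covering every
#'   chromosome present in the inputs.
#' @return `enrichment_result` as in [gene_set_overlap_test()] with counts
#'   in bp.
#' @export
interval_overlap_test <- function(query, reference, genome_sizes) {
  chroms <- unique(c(query$chrom, reference$chrom))
  missing_chr <- setdiff(chroms, names(genome_sizes))
  if (length(missing_chr))
    stop("genome_sizes missing chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  for (rs in list(query, reference)) {
    if (nrow(rs) && any(rs$end > genome_sizes[rs$chrom]))
      stop("interval exceeds chromosome length")
  }
  N <- sum(genome_sizes)
  if (nrow(query) == 0L || nrow(reference) == 0L) {
    warning("degenerate overlap table (empty query or reference)")
    qbp <- if (nrow(query)) sum(IRanges::width(GenomicRanges::reduce(regions_to_gr(query)))) else 0
    rbp <- if (nrow(reference)) sum(IRanges::width(GenomicRanges::reduce(regions_to_gr(reference)))) else 0
    return(structure(list(a = 0, b = qbp, c = rbp, d = N - qbp - rbp,
                          odds_ratio = NA_real_, odds_ratio_mle = NA_real_,
                          p_one_sided = 1, p_two_sided = 1, universe_n = N),
                     class = "enrichment_result"))
  }
  qg <- GenomicRanges::reduce(regions_to_gr(query), ignore.strand = TRUE)
  rg <- GenomicRanges::reduce(regions_to_gr(reference), ignore.strand = TRUE)
  both <- sum(IRanges::width(GenomicRanges::intersect(qg, rg, ignore.strand = TRUE)))
  qbp <- sum(IRanges::width(qg)) - both
  rbp <- sum(IRanges::width(rg)) - both
  d <- N - both - qbp - rbp
  p1 <- phyper(both - 1, both + rbp, N - both - rbp, both + qbp,
               lower.tail = FALSE)
  ft <- fisher.test(matrix(c(both, qbp, rbp, d), 2L, byrow = TRUE))
  structure(list(a = both, b = qbp, c = rbp, d = d,
                 odds_ratio = (both * d) / max(qbp * rbp, 1),
                 odds_ratio_mle = unname(ft$estimate),
                 p_one_sided = p1, p_two_sided = ft$p.value, universe_n = N),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2:", x$a, x$b, "/", x$c, x$d, " OR:", signif(x$odds_ratio, 3),
      " p(one-sided):", signif(x$p_one_sided, 3),
      " p(two-sided):", signif(x$p_two_sided, 3), "\n")
  invisible(x)
}

#' Percentage at printed precision
#'
#' 100 * numerator / denominator, rounded the way such fractions are
#' printed: to the nearest integer when the percentage is >= 10, to one
#' decimal below 10.
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @return numeric percentage.
#' @export
summarize_fraction <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  pct <- 100 * numerator / denominator
  if (pct >= 10) round(pct) else round(pct, 1)
}
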