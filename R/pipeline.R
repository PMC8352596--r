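# Orchestration: one config (R list or YAML file) drives the stages in
# dependency order: ingest -> QC/methylation -> DMC/DMR -> profiles ->
# cluster -> coexpr -> enrich. Reruns with the same config and seed are
# bit-identical for the deterministic stages.

default_params <- function() {
  list(fdr = 0.01, cov_min = 4L, window = 500L,
       min_dmcs_cg = 8L, min_dmcs_noncg = 4L,
       flank = 1500L, k = 4L, top_n = 25L, iterations = 1000L,
       n_up = 10L, n_body = 20L, n_down = 10L,
       te_cov_min = 4L, te_min_sites = 5L, gene_min_reads = 5L)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$params <- utils::modifyList(default_params(), config$params %||% list())
  config
}

validate_pipeline_config <- function(config) {
  req <- c("input_dir", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
  stages <- config$stages %||% c("methylation", "dmr", "profiles",
                                 "cluster", "coexpr", "enrich")
  fp <- function(x) file.path(config$input_dir, x)
  if (!file.exists(fp("genes.bed"))) stop("stage ingest: missing genes.bed")
  allc <- list.files(config$input_dir, "^allc_.*\\.tsv$")
  if (length(allc) < 2L) stop("stage ingest: need >= 2 allc_*.tsv methylomes")
  if ("coexpr" %in% stages && !file.exists(fp("expression.tsv")))
    stop("stage coexpr: missing expression.tsv")
  if ("profiles" %in% stages && !file.exists(fp("centromeres.tsv")))
    stop("stage profiles: missing centromeres.tsv")
  invisible(stages)
}

provenance_header <- function(config, seed) {
  cfg_hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
  sprintf("# methdyn %s config_hash=%d seed=%d",
          as.character(utils::packageVersion("methdyn")), as.integer(cfg_hash),
          as.integer(seed))
}

write_tsv_with_header <- function(dt, path, header) {
  writeLines(header, path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
}

#' Run the full analysis pipeline from a config
#'
#' The config (R list or YAML path) names an input directory in the bundle
#' layout written by [generate_full_study()] (`allc_*.tsv` methylomes,
#' `genes.bed`, `tes.bed`, `centromeres.tsv`, `genome_sizes.tsv`,
#' `expression.tsv`) plus `out_dir`, optional `seed`, `groups` (replicate
#' pooling map), `contrast` (two pooled sample ids, mutant first) and
#' `params` overrides. Artifacts are TSV/BED files carrying a provenance
#' header line (package version, config hash, seed).
#'
#' @param config list or YAML file path.
#' @return invisible list of produced artifact paths, by stage.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  stages <- validate_pipeline_config(config)
  p <- config$params
  seed <- config$seed %||% 1L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(config, seed)
  fp <- function(x) file.path(config$input_dir, x)
  op <- function(x) file.path(config$out_dir, x)
  artifacts <- list()
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  ## ingest
  msg("ingest", "reading annotations and methylomes")
  genes <- read_regions(fp("genes.bed"), "bed", kind = "gene")
  tes <- if (file.exists(fp("tes.bed")))
    read_regions(fp("tes.bed"), "bed", kind = "TE") else region_set()
  allc <- list.files(config$input_dir, "^allc_.*\\.tsv$", full.names = TRUE)
  ids <- sub("^allc_(.*)\\.tsv$", "\\1", basename(allc))
  tabs <- setNames(lapply(allc, read_cytosine_table), ids)
  samples <- sample_set(tabs)
  sizes_dt <- fread(fp("genome_sizes.tsv"))
  genome_sizes <- setNames(sizes_dt$length, sizes_dt$chrom)
  groups <- config$groups %||%
    setNames(as.list(ids), ids)            # default: no pooling
  pooled <- pool_replicates(samples, groups)
  contrast <- config$contrast %||% names(pooled$tables)[1:2]

  ## methylation / QC
  if ("methylation" %in% stages) {
    msg("methylation", "conversion QC and region methylation")
    ctl <- config$control_chrom %||% "ChrC"
    qc <- data.table(sample_id = names(samples$tables),
                     conversion_rate = vapply(samples$tables, conversion_rate,
                                              numeric(1L), control_chrom = ctl))
    write_tsv_with_header(qc, op("conversion_qc.tsv"), hdr)
    for (ctx in CONTEXTS) {
      rm_ <- rbindlist(lapply(names(pooled$tables), function(id)
        cbind(sample_id = id,
              region_methylation(pooled$tables[[id]], genes, ctx))))
      write_tsv_with_header(rm_, op(paste0("gene_methylation_", ctx, ".tsv")), hdr)
    }
    artifacts$methylation <- op("conversion_qc.tsv")
  }

  ## DMC / DMR
  dmrs_by_ctx <- list()
  if ("dmr" %in% stages) {
    for (ctx in CONTEXTS) {
      msg("dmr", "calling ", ctx, " DMCs (fdr=", p$fdr, ", cov_min=", p$cov_min, ")")
      dmcs <- call_dmcs(pooled, ctx, fdr = p$fdr, cov_min = p$cov_min,
                        seed = seed)
      cls <- if (ctx == "CG") "CG" else "nonCG"
      mind <- if (ctx == "CG") p$min_dmcs_cg else p$min_dmcs_noncg
      dmrs <- collapse_dmrs(dmcs, cls, window = p$window, min_dmcs = mind)
      dmrs_by_ctx[[ctx]] <- dmrs
      msg("dmr", nrow(dmrs), " ", ctx, " DMRs")
      if (nrow(dmrs)) {
        write_regions(dmrs, op(paste0("dmrs_", ctx, ".bed")))
        rates <- methylation_matrix(pooled, dmrs, ctx)
        write_tsv_with_header(
          data.table(label = dmrs$label, n_dmcs = dmrs$n_dmcs,
                     as.data.table(rates)),
          op(paste0("dmrs_", ctx, ".tsv")), hdr)
      }
    }
    artifacts$dmr <- op("dmrs_CHG.bed")
  }

  ## profiles
  if ("profiles" %in% stages) {
    msg("profiles", "metagene profiles and centromere percentiles")
    tA <- pooled$tables[[contrast[1L]]]
    tB <- pooled$tables[[contrast[2L]]]
    mp <- metaprofile(tA, genes, "CHG", p$n_up, p$n_body, p$n_down, p$flank)
    write_tsv_with_header(
      data.table(bin = seq_along(mp$values), mean = mp$values,
                 sd = mp$spread, n = mp$n_regions),
      op("metaprofile_CHG.tsv"), hdr)
    cen <- fread(fp("centromeres.tsv"))
    pct <- tryCatch(
      centromere_percentiles(tA, tB, "CG", 1000L, cen,
                             genome_sizes[names(genome_sizes) !=
                                            (config$control_chrom %||% "ChrC")]),
      error = function(e) { msg("profiles", "skipping percentiles: ",
                                conditionMessage(e)); NULL })
    if (!is.null(pct))
      write_tsv_with_header(pct, op("centromere_percentiles.tsv"), hdr)
    artifacts$profiles <- op("metaprofile_CHG.tsv")
  }

  ## cluster
  assign <- NULL
  if ("cluster" %in% stages) {
    msg("cluster", "k-means on methylation-difference profiles (k=", p$k, ")")
    prof <- difference_profiles(pooled$tables[[contrast[1L]]],
                                pooled$tables[[contrast[2L]]],
                                genes, "CHG", p$n_up, p$n_body, p$n_down,
                                p$flank, min_reads = p$gene_min_reads)
    assign <- kmeans_partition(prof, k = p$k, seed = seed)
    write_tsv_with_header(
      data.table(gene = names(assign$cluster), cluster = assign$cluster),
      op("gene_clusters.tsv"), hdr)
    artifacts$cluster <- op("gene_clusters.tsv")
  }

  ## coexpr
  if ("coexpr" %in% stages) {
    msg("coexpr", "centroid neighbours and permutation baseline")
    edt <- fread(fp("expression.tsv"))
    expr <- as.matrix(edt[, -1L])
    rownames(expr) <- edt[[1L]]
    seeds <- config$seed_genes %||% rownames(expr)[1:4]
    nb <- centroid_neighbors(expr, seeds, top_n = p$top_n)
    bl <- permutation_baseline(expr, set_size = p$top_n,
                               iterations = p$iterations, seed = seed)
    write_tsv_with_header(nb$ranked, op("neighbors.tsv"), hdr)
    write_tsv_with_header(
      data.table(sample = colnames(bl$medians),
                 grand_median = bl$grand_median, se = bl$se),
      op("baseline.tsv"), hdr)
    artifacts$coexpr <- op("neighbors.tsv")
  }

  ## enrich
  if ("enrich" %in% stages && length(dmrs_by_ctx)) {
    msg("enrich", "DMR-gene association (flank=", p$flank, ")")
    dmrs <- dmrs_by_ctx[["CHG"]]
    if (!is.null(dmrs) && nrow(dmrs)) {
      links <- associate_dmrs_genes(dmrs, genes, flank = p$flank)
      write_tsv_with_header(links, op("dmr_gene_links.tsv"), hdr)
      artifacts$enrich <- op("dmr_gene_links.tsv")
    }
  }
  invisible(artifacts)
}
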