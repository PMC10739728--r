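pipeline_stages <- c("simulate", "qc", "normalize", "hvg", "cluster",
                     "markers", "project", "repertoire", "lineage", "report")

stage_paths <- function(outdir) {
  list(
    counts = file.path(outdir, "01_counts"),
    contigs = file.path(outdir, "01_counts", "contigs.csv"),
    truth = file.path(outdir, "01_counts"),
    qc = file.path(outdir, "02_qc", "qc_report.tsv"),
    filtered = file.path(outdir, "02_qc", "filtered"),
    norm = file.path(outdir, "03_normalized"),
    hvg = file.path(outdir, "04_hvg", "hvg_table.tsv"),
    embedding = file.path(outdir, "05_cluster", "embedding.tsv"),
    markers = file.path(outdir, "06_markers", "markers.tsv"),
    projection = file.path(outdir, "07_projection", "projection.tsv"),
    ratios = file.path(outdir, "07_projection", "mapping_ratios.tsv"),
    clonotypes = file.path(outdir, "08_repertoire", "clonotypes.tsv"),
    diversity = file.path(outdir, "08_repertoire", "diversity.tsv"),
    overlap = file.path(outdir, "08_repertoire", "overlap_pairs.tsv"),
    shared = file.path(outdir, "08_repertoire", "shared_clones.tsv"),
    spectra_len = file.path(outdir, "08_repertoire", "cdr3_lengths.tsv"),
    spectra_freq = file.path(outdir, "08_repertoire", "cdr3_freq_matrix.tsv"),
    lineage = file.path(outdir, "09_lineage", "lineage.json"),
    pseudotime = file.path(outdir, "09_lineage", "pseudotime.tsv"),
    report = file.path(outdir, "run_report.json")
  )
}

write_norm_dir <- function(norm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(norm$mat, sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(dir, "matrix_norm.mtx"))
  readr::write_tsv(norm$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(dplyr::mutate(norm$cells, size_factor = norm$size_factors,
                                 pseudocount = norm$pseudocount),
                   file.path(dir, "cells.tsv"))
}

read_norm_dir <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix_norm.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  sc_norm(m, cells$size_factor, cells$pseudocount[1], genes,
          dplyr::select(cells, -"size_factor", -"pseudocount"))
}

require_artifact <- function(path, stage_needed) {
  if (!all(file.exists(path))) {
    abort(sprintf("missing artifact %s; run stage '%s' first (or point --outdir at an existing run)",
                  path[!file.exists(path)][1], stage_needed),
          class = "inktatlas_missing_stage")
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates `simulate -> qc -> normalize -> hvg -> cluster -> markers ->
#' project -> repertoire -> lineage -> report` from one configuration.
#' Every stage persists its outputs in open formats (MTX/TSV/CSV/JSON)
#' under `outdir`, so partial runs resume from disk and any intermediate is
#' independently inspectable. The first simulated tissue serves as the
#' reference (clustered and embedded); cells from the remaining tissues are
#' the query projected onto it. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param stages character vector of stages to run (default: all, in
#'   dependency order).
#' @param sim a [sim_params()] for the simulate stage (default: the
#'   standard two-tissue design with the config's seed).
#' @return The run report (a list), invisibly written as JSON.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = pipeline_stages,
                         sim = sim_params(seed = config$seed)) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) abort(paste("unknown stage:", bad[1]),
                         class = "inktatlas_param_error")
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage_paths(outdir)
  counts_summary <- list()
  warnings <- character(0)
  note <- function(stage, w) {
    warnings <<- c(warnings, paste0(stage, ": ", w))
  }
  cache <- new.env(parent = emptyenv())

  get_filtered <- function() {
    if (is.null(cache$filtered)) {
      require_artifact(file.path(paths$filtered, "matrix.mtx"), "qc")
      cache$filtered <- read_counts_mtx(paths$filtered,
                                        mito_prefix = config$mito_prefix)
    }
    cache$filtered
  }
  get_norm <- function() {
    if (is.null(cache$norm)) {
      require_artifact(file.path(paths$norm, "matrix_norm.mtx"), "normalize")
      cache$norm <- read_norm_dir(paths$norm)
    }
    cache$norm
  }
  get_hvg <- function() {
    if (is.null(cache$hvg)) {
      require_artifact(paths$hvg, "hvg")
      cache$hvg <- readr::read_tsv(paths$hvg, show_col_types = FALSE)
    }
    cache$hvg
  }
  get_embedding <- function() {
    if (is.null(cache$embedding)) {
      require_artifact(paths$embedding, "cluster")
      tab <- readr::read_tsv(paths$embedding, show_col_types = FALSE)
      pc_cols <- grep("^PC", names(tab), value = TRUE)
      cache$embedding <- sc_embedding(
        pcs = as.matrix(tab[, pc_cols]),
        umap = as.matrix(tab[, c("UMAP1", "UMAP2")]),
        cluster = tab$cluster, barcodes = tab$barcode)
    }
    cache$embedding
  }
  ref_tissue <- colnames(sim$subpop_spec)[1]
  split_ref <- function(norm) {
    is_ref <- norm$cells$tissue == ref_tissue
    list(ref = subset_norm(norm, is_ref), query = subset_norm(norm, !is_ref),
         is_ref = is_ref)
  }

  if ("simulate" %in% stages) {
    ds <- simulate_dataset(sim)
    write_counts_mtx(ds$counts, paths$counts)
    write_contigs_csv(ds$contigs, paths$contigs)
    write_truth_tsv(ds$truth, paths$truth)
    cache$raw <- ds$counts
    counts_summary$simulate <- list(n_genes = nrow(ds$counts$counts),
                                    n_cells = ncol(ds$counts$counts),
                                    n_contigs = nrow(ds$contigs))
  }
  if ("qc" %in% stages) {
    if (is.null(cache$raw)) {
      require_artifact(file.path(paths$counts, "matrix.mtx"), "simulate")
      cache$raw <- read_counts_mtx(paths$counts,
                                   mito_prefix = config$mito_prefix)
    }
    res <- withCallingHandlers(
      filter_cells(cache$raw, config),
      warning = function(w) { note("qc", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    dir.create(dirname(paths$qc), recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(res$qc, paths$qc)
    write_counts_mtx(res$counts, paths$filtered)
    cache$filtered <- res$counts
    counts_summary$qc <- list(n_in = nrow(res$qc), n_kept = sum(res$qc$kept))
  }
  if ("normalize" %in% stages) {
    filt <- get_filtered()
    sf <- compute_size_factors(filt)
    cache$norm <- lognormalize(filt, sf, config)
    write_norm_dir(cache$norm, paths$norm)
    counts_summary$normalize <- list(n_cells = ncol(cache$norm$mat))
  }
  if ("hvg" %in% stages) {
    sp <- split_ref(get_norm())
    hvg <- select_hvgs(sp$ref, config)
    dir.create(dirname(paths$hvg), recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(hvg, paths$hvg)
    cache$hvg <- hvg
    counts_summary$hvg <- list(n_genes = nrow(hvg),
                               n_selected = sum(hvg$selected))
  }
  if ("cluster" %in% stages) {
    sp <- split_ref(get_norm())
    emb <- cluster_embed(sp$ref, get_hvg(), config)
    dir.create(dirname(paths$embedding), recursive = TRUE,
               showWarnings = FALSE)
    readr::write_tsv(tidy(emb), paths$embedding)
    cache$embedding <- emb
    counts_summary$cluster <- list(n_cells = nrow(emb$pcs),
                                   n_clusters = length(unique(emb$cluster)))
  }
  if ("markers" %in% stages) {
    sp <- split_ref(get_norm())
    emb <- get_embedding()
    mk <- withCallingHandlers(
      find_markers(sp$ref, emb$cluster, config$pseudocount),
      warning = function(w) { note("markers", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    dir.create(dirname(paths$markers), recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(mk, paths$markers)
    counts_summary$markers <- list(n_rows = nrow(mk))
  }
  if ("project" %in% stages) {
    sp <- split_ref(get_norm())
    emb <- get_embedding()
    proj <- withCallingHandlers(
      project_cells(sp$ref, emb, get_hvg(), sp$query, config),
      warning = function(w) { note("project", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    ratios <- mapping_ratio(proj, group_by = sp$query$cells$tissue)
    dir.create(dirname(paths$projection), recursive = TRUE,
               showWarnings = FALSE)
    flat <- dplyr::mutate(
      proj,
      neighbors = purrr::map_chr(.data$neighbors, paste, collapse = ","),
      correlations = purrr::map_chr(.data$correlations,
                                    ~ paste(signif(.x, 10), collapse = ",")))
    readr::write_tsv(flat, paths$projection)
    readr::write_tsv(ratios, paths$ratios)
    counts_summary$project <- list(n_query = nrow(proj),
                                   n_mapped = sum(proj$mappable))
  }
  if ("repertoire" %in% stages) {
    require_artifact(paths$contigs, "simulate")
    filt <- get_filtered()
    emb <- get_embedding()
    contigs <- filter_contigs(read_contigs_csv(paths$contigs))
    clono <- withCallingHandlers(
      call_clonotypes(contigs, emb$barcodes),
      warning = function(w) { note("repertoire", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    groups <- paste0("C", emb$cluster)
    div <- repertoire_diversity(clono, groups)
    ov <- withCallingHandlers(
      clonotype_overlap(clono, groups),
      warning = function(w) { note("repertoire", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    spec <- cdr3_spectratype(clono)
    dir.create(dirname(paths$clonotypes), recursive = TRUE,
               showWarnings = FALSE)
    readr::write_tsv(clono, paths$clonotypes)
    readr::write_tsv(div, paths$diversity)
    readr::write_tsv(ov$pairs, paths$overlap)
    readr::write_tsv(ov$shared_clones, paths$shared)
    readr::write_tsv(spec$lengths, paths$spectra_len)
    freq <- as_tibble(spec$freq_matrix, rownames = "aa")
    readr::write_tsv(freq, paths$spectra_freq)
    counts_summary$repertoire <- list(
      n_assigned = sum(!is.na(clono$clonotype_id)),
      n_clonotypes = length(unique(stats::na.omit(clono$clonotype_id))))
  }
  if ("lineage" %in% stages) {
    emb <- get_embedding()
    start <- min(emb$cluster)
    lg <- infer_lineages(emb, start = start)
    pt <- pseudotime(lg, emb)
    dir.create(dirname(paths$lineage), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(start = lg$start, ends = lg$ends,
           edges = lg$edges,
           lineages = lapply(lg$lineages, identity)),
      paths$lineage, auto_unbox = TRUE, digits = NA)
    readr::write_tsv(pt, paths$pseudotime)
    counts_summary$lineage <- list(n_lineages = length(lg$lineages))
  }

  manifest <- NULL
  if ("report" %in% stages) {
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, paths$report)
    manifest <- tibble(file = sub(paste0("^", outdir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)))
  }
  report <- list(config = unclass(config), seed = config$seed,
                 stages = stages, stage_summaries = counts_summary,
                 warnings = warnings,
                 manifest = manifest)
  if ("report" %in% stages) {
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Subset an [sc_norm] by cells
#'
#' @param norm an [sc_norm].
#' @param cells logical or integer cell index.
#' @return The subsetted [sc_norm].
#' @export
subset_norm <- function(norm, cells) {
  sc_norm(norm$mat[, cells, drop = FALSE], norm$size_factors[cells],
          norm$pseudocount, norm$genes, norm$cells[cells, , drop = FALSE])
}
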