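#' Pipeline configuration
#'
#' Holds the fixed analysis parameters: the QC thresholds (cells with fewer
#' than `min_umi` UMIs or more than `max_mito_fraction` mitochondrial UMI
#' fraction are excluded, both as strict inequalities), the HVG FDR cutoff,
#' the number of principal components, the clustering resolution, the number
#' of nearest neighbours used for reference projection, and normalization
#' settings.
#'
#' @param min_umi minimum total UMIs per cell; cells with fewer are excluded
#'   (default 1000).
#' @param max_mito_fraction maximum mitochondrial UMI fraction; cells above
#'   it are excluded (default 0.10).
#' @param hvg_fdr FDR threshold for highly variable gene selection
#'   (default 0.05).
#' @param n_pcs number of principal components (default 15).
#' @param cluster_resolution modularity resolution for graph clustering
#'   (default 0.8).
#' @param k_project neighbours used in correlation-kNN projection
#'   (default 5).
#' @param pseudocount pseudocount added before the log2 transform
#'   (default 1).
#' @param de_correction multiple-testing correction for condition-wise
#'   differential expression: `"bonferroni"` or `"bh"`.
#' @param mito_prefix case-insensitive mitochondrial gene-name prefix.
#' @param snn_k neighbours used to build the shared-nearest-neighbor graph.
#' @param seed master seed for the stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_umi = 1000,
                            max_mito_fraction = 0.10,
                            hvg_fdr = 0.05,
                            n_pcs = 15,
                            cluster_resolution = 0.8,
                            k_project = 5,
                            pseudocount = 1,
                            de_correction = c("bonferroni", "bh"),
                            mito_prefix = "mt-",
                            snn_k = 20,
                            seed = 1L) {
  cfg <- list(min_umi = min_umi, max_mito_fraction = max_mito_fraction,
              hvg_fdr = hvg_fdr, n_pcs = as.integer(n_pcs),
              cluster_resolution = cluster_resolution,
              k_project = as.integer(k_project),
              pseudocount = pseudocount, log_base = 2,
              de_correction = match.arg(de_correction),
              mito_prefix = mito_prefix, snn_k = as.integer(snn_k),
              seed = as.integer(seed))
  if (cfg$min_umi < 0 || cfg$max_mito_fraction < 0 ||
      cfg$max_mito_fraction > 1 || cfg$k_project < 1 || cfg$n_pcs < 2) {
    abort("invalid pipeline configuration", class = "inktatlas_param_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read/write a flat key-value config file
#'
#' The config format is one `key = value` pair per line; `#` starts a
#' comment. Unknown keys raise an error.
#'
#' @param path file path.
#' @return For `read_config()`, a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste("malformed config line:", lines[bad][1]),
                      class = "inktatlas_format_error")
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(unclass(defaults)))
  if (length(unknown)) abort(paste("unknown config key:", unknown[1]),
                             class = "inktatlas_format_error")
  args <- stats::setNames(as.list(vals), keys)
  for (k in names(args)) {
    if (!k %in% c("de_correction", "mito_prefix")) {
      args[[k]] <- as.numeric(args[[k]])
    }
  }
  args$log_base <- NULL
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, as.character, "")), path)
  invisible(path)
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, 1-based),
#' `features.tsv` (gene id, gene name, feature type) and `barcodes.tsv`,
#' plus `cell_metadata.tsv` if the cell table has columns beyond the
#' barcode.
#'
#' @param x an [sc_counts].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene_id = x$genes$gene_id,
                          gene_name = x$genes$gene_id,
                          feature_type = "Gene Expression"),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = x$cells$barcode),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  if (ncol(x$cells) > 1) {
    readr::write_tsv(x$cells, file.path(dir, "cell_metadata.tsv"))
  }
  invisible(dir)
}

#' Read a 10x-style MTX triplet into an [sc_counts]
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv` and
#'   `barcodes.tsv` (and optionally `cell_metadata.tsv`).
#' @param mito_prefix case-insensitive mitochondrial gene-name prefix.
#' @return An [sc_counts].
#' @export
read_counts_mtx <- function(dir, mito_prefix = "mt-") {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- !file.exists(paths)
  if (any(missing)) abort(paste("missing file:", paths[missing][1]),
                          class = "inktatlas_format_error")
  m <- Matrix::readMM(paths[1])
  feats <- readr::read_tsv(paths[2], col_names = FALSE,
                           show_col_types = FALSE)
  bcs <- readr::read_tsv(paths[3], col_names = FALSE,
                         show_col_types = FALSE)[[1]]
  if (nrow(feats) != nrow(m) || length(bcs) != ncol(m)) {
    abort("MTX dimensions do not match features/barcodes",
          class = "inktatlas_format_error")
  }
  if (anyDuplicated(bcs)) abort("duplicate barcodes",
                                class = "inktatlas_format_error")
  if (any(m@x != round(m@x)) || any(m@x < 0)) {
    abort("non-integer or negative values in count MTX",
          class = "inktatlas_format_error")
  }
  cells <- tibble(barcode = bcs)
  meta_path <- file.path(dir, "cell_metadata.tsv")
  if (file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
    if (!identical(meta$barcode, bcs)) {
      abort("cell_metadata.tsv barcodes do not match barcodes.tsv",
            class = "inktatlas_format_error")
    }
    cells <- as_tibble(meta)
  }
  sc_counts(m, tibble(gene_id = feats[[1]]), cells,
            mito_prefix = mito_prefix)
}

contig_required_cols <- c("barcode", "is_cell", "high_confidence", "chain",
                          "v_gene", "j_gene", "cdr3", "productive", "umis")

# 10x emits "True"/"False"/"None"; anything but a case-insensitive true is
# treated as false.
parse_contig_bool <- function(x) tolower(as.character(x)) == "true"

#' Read V(D)J contig annotations
#'
#' Parses the 10x `filtered_contig_annotations.csv` dialect. Boolean columns
#' accept `"True"`/`"true"`/`"TRUE"`; any other value (including `"None"`)
#' parses as `FALSE`.
#'
#' @param path CSV file path.
#' @return A tibble with one row per contig.
#' @export
read_contigs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(contig_required_cols, names(df))
  if (length(missing)) {
    abort(paste("missing contig column:", paste(missing, collapse = ", ")),
          class = "inktatlas_format_error")
  }
  tibble(barcode = df$barcode,
         is_cell = parse_contig_bool(df$is_cell),
         high_confidence = parse_contig_bool(df$high_confidence),
         chain = df$chain,
         v_gene = df$v_gene,
         j_gene = df$j_gene,
         cdr3 = df$cdr3,
         productive = parse_contig_bool(df$productive),
         umis = as.integer(df$umis))
}

#' @rdname read_contigs_csv
#' @param contigs tibble of contig records.
#' @export
write_contigs_csv <- function(contigs, path) {
  out <- contigs[, contig_required_cols]
  out$is_cell <- ifelse(out$is_cell, "True", "False")
  out$high_confidence <- ifelse(out$high_confidence, "True", "False")
  out$productive <- ifelse(out$productive, "True", "False")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write the ground-truth tables of a simulation
#'
#' @param truth the truth component of [simulate_counts()]/[simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth_tsv <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(truth$cells, file.path(dir, "truth_cells.tsv"))
  readr::write_tsv(truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
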