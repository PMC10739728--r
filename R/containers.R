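#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import Matrix
NULL

#' Single-cell count container
#'
#' Bundles a sparse gene-by-cell integer UMI matrix with gene and cell
#' metadata tibbles. Gene metadata carries the mitochondrial flag (gene
#' name prefix match, case-insensitive); cell metadata carries at least
#' `barcode`, and typically `tissue` and `condition`.
#'
#' @param counts gene-by-cell matrix (coerced to `dgCMatrix`); integer values.
#' @param genes tibble with one row per gene; must contain `gene_id`.
#'   An `is_mito` column is added from `mito_prefix` if absent.
#' @param cells tibble with one row per cell; must contain `barcode`.
#' @param mito_prefix case-insensitive gene-name prefix marking
#'   mitochondrial genes (default `"mt-"`).
#' @return An `sc_counts` object.
#' @export
sc_counts <- function(counts, genes, cells, mito_prefix = "mt-") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  genes <- as_tibble(genes)
  cells <- as_tibble(cells)
  if (!"gene_id" %in% names(genes)) abort("`genes` needs a gene_id column")
  if (!"barcode" %in% names(cells)) abort("`cells` needs a barcode column")
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts)) {
    abort("metadata dimensions do not match the count matrix")
  }
  if (anyDuplicated(cells$barcode)) abort("duplicate cell barcodes")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("counts must be nonnegative integers")
  }
  if (!"is_mito" %in% names(genes)) {
    genes$is_mito <- is_mito_gene(genes$gene_id, mito_prefix)
  }
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "sc_counts")
}

is_mito_gene <- function(gene_id, mito_prefix = "mt-") {
  startsWith(tolower(gene_id), tolower(mito_prefix))
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' @exportS3Method base::print
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d genes x %d cells (%d mito genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$genes$is_mito)))
  invisible(x)
}

#' Log-normalized expression container
#'
#' Holds the dense log2 size-factor-normalized matrix together with the
#' size-factor vector and the pseudocount used, so the transform is
#' invertible.
#'
#' @param mat gene-by-cell numeric matrix of log2 values.
#' @param size_factors per-cell positive size factors (unit mean).
#' @param pseudocount pseudocount used in the transform.
#' @param genes,cells metadata tibbles carried over from the counts.
#' @return An `sc_norm` object.
#' @export
sc_norm <- function(mat, size_factors, pseudocount, genes, cells) {
  structure(list(mat = mat, size_factors = size_factors,
                 pseudocount = pseudocount,
                 genes = as_tibble(genes), cells = as_tibble(cells)),
            class = "sc_norm")
}

#' @export
dim.sc_norm <- function(x) dim(x$mat)

#' @exportS3Method base::print
print.sc_norm <- function(x, ...) {
  cat(sprintf("<sc_norm> %d genes x %d cells, pseudocount %g\n",
              nrow(x$mat), ncol(x$mat), x$pseudocount))
  invisible(x)
}

#' Embedding container
#'
#' Per-cell principal components, 2-D UMAP coordinates and cluster labels
#' (contiguous integers from 0), plus PC loadings and explained variance
#' for reproducibility.
#'
#' @param pcs cells-by-PCs matrix.
#' @param umap cells-by-2 matrix.
#' @param cluster integer vector of labels in `0..K-1`.
#' @param barcodes cell barcodes.
#' @param loadings genes-by-PCs loading matrix.
#' @param sdev per-component standard deviations.
#' @return An `sc_embedding` object.
#' @export
sc_embedding <- function(pcs, umap = NULL, cluster = NULL, barcodes,
                         loadings = NULL, sdev = NULL) {
  structure(list(pcs = pcs, umap = umap, cluster = cluster,
                 barcodes = barcodes, loadings = loadings, sdev = sdev),
            class = "sc_embedding")
}

#' @exportS3Method base::print
print.sc_embedding <- function(x, ...) {
  k <- if (is.null(x$cluster)) NA_integer_ else length(unique(x$cluster))
  cat(sprintf("<sc_embedding> %d cells, %d PCs, %s clusters, umap: %s\n",
              nrow(x$pcs), ncol(x$pcs), k, !is.null(x$umap)))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an embedding into one row per cell
#'
#' @param x an `sc_embedding`.
#' @param ... unused.
#' @return A tibble with barcode, PC coordinates, UMAP coordinates and
#'   cluster label.
#' @export
tidy.sc_embedding <- function(x, ...) {
  out <- as_tibble(x$pcs, .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(ncol(out)))
  out <- dplyr::bind_cols(tibble(barcode = x$barcodes), out)
  if (!is.null(x$umap)) {
    out$UMAP1 <- x$umap[, 1]
    out$UMAP2 <- x$umap[, 2]
  }
  if (!is.null(x$cluster)) out$cluster <- x$cluster
  out
}

#' One-row summary of an embedding
#'
#' @param x an `sc_embedding`.
#' @param ... unused.
#' @return A tibble with cell count, PC count, cluster count and the
#'   variance explained by the retained components.
#' @export
glance.sc_embedding <- function(x, ...) {
  tibble(
    n_cells = nrow(x$pcs),
    n_pcs = ncol(x$pcs),
    n_clusters = if (is.null(x$cluster)) NA_integer_
                 else length(unique(x$cluster)),
    var_explained = if (is.null(x$sdev)) NA_real_
                    else sum(x$sdev[seq_len(ncol(x$pcs))]^2) / sum(x$sdev^2)
  )
}
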