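#' Principal-component reduction of the HVG submatrix
#'
#' Centers (and unit-scales) each selected gene across cells and projects
#' cells onto the top `config$n_pcs` components. Component signs are fixed
#' by making the largest-magnitude loading entry of each component
#' positive, so results are reproducible across platforms.
#'
#' @param norm an [sc_norm].
#' @param hvgs the tibble from [select_hvgs()] (only rows with
#'   `selected == TRUE` are used), or a character vector of gene ids.
#' @param config a [pipeline_config()].
#' @param scale. unit-scale genes before the rotation (default `TRUE`).
#' @return An [sc_embedding] with `pcs`, `loadings` and `sdev` filled in.
#' @export
reduce_pca <- function(norm, hvgs, config = pipeline_config(),
                       scale. = TRUE) {
  stopifnot(inherits(norm, "sc_norm"))
  genes <- if (is.character(hvgs)) hvgs else hvgs$gene_id[hvgs$selected]
  genes <- intersect(genes, norm$genes$gene_id)
  if (length(genes) < config$n_pcs) {
    abort(sprintf("need at least n_pcs = %d selected genes, got %d",
                  config$n_pcs, length(genes)),
          class = "inktatlas_param_error")
  }
  x <- t(norm$mat[match(genes, norm$genes$gene_id), , drop = FALSE])
  if (config$n_pcs > min(dim(x))) {
    abort("n_pcs exceeds the matrix rank bound",
          class = "inktatlas_param_error")
  }
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE], center = TRUE,
             scale = if (scale.) sds[keep] else FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- config$n_pcs
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- x %*% rot
  colnames(scores) <- paste0("PC", seq_len(k))
  sc_embedding(pcs = scores, barcodes = norm$cells$barcode,
               loadings = rot, sdev = pc$sdev)
}

# kNN (k excl. self) + shared-nearest-neighbor Jaccard weights between all
# cell pairs whose neighbourhoods (incl. self) overlap enough. Pruning
# mirrors the common 1/15 default.
snn_graph <- function(pcs, k = 20, prune = 1/15) {
  n <- nrow(pcs)
  k <- min(k, n - 1)
  nn <- FNN::get.knn(pcs, k = k)$nn.index
  inc <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                              j = c(seq_len(n), as.vector(nn)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(inc)     # neighbourhood intersection sizes
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  w <- s / (2 * (k + 1) - s)
  sel <- w >= prune
  igraph::graph_from_data_frame(
    data.frame(from = i[sel], to = j[sel], weight = w[sel]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' Graph-based clustering in PC space
#'
#' Builds a shared-nearest-neighbor graph (k = `config$snn_k`, Jaccard edge
#' weights) over cells in PC space and partitions it by modularity
#' community detection at `config$cluster_resolution`. Deterministic given
#' `config$seed`. Labels are contiguous integers from 0, ordered by
#' decreasing cluster size.
#'
#' @param embedding an [sc_embedding] (from [reduce_pca()]) or a
#'   cells-by-PCs matrix.
#' @param config a [pipeline_config()].
#' @return The embedding with `cluster` filled in (or, for a matrix input,
#'   the label vector).
#' @export
cluster_snn <- function(embedding, config = pipeline_config()) {
  pcs <- if (inherits(embedding, "sc_embedding")) embedding$pcs else embedding
  if (nrow(pcs) < 2) abort("need at least 2 cells",
                           class = "inktatlas_param_error")
  g <- snn_graph(pcs, k = config$snn_k)
  labels <- withr::with_seed(config$seed, {
    comm <- igraph::cluster_louvain(g, resolution = config$cluster_resolution)
    igraph::membership(comm)
  })
  # relabel 0-based by decreasing size; ties by first appearance
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(labels)])
  if (inherits(embedding, "sc_embedding")) {
    embedding$cluster <- out
    embedding
  } else {
    out
  }
}

#' 2-D UMAP embedding of the PC coordinates
#'
#' Deterministic given `config$seed` (single-threaded layout). The
#' coordinates are stored with the reference embedding so query cells can
#' later be projected onto them.
#'
#' @param embedding an [sc_embedding] or a cells-by-PCs matrix.
#' @param config a [pipeline_config()].
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return The embedding with `umap` filled in (or the coordinate matrix).
#' @export
embed_2d <- function(embedding, config = pipeline_config(),
                     n_neighbors = 15, min_dist = 0.3) {
  pcs <- if (inherits(embedding, "sc_embedding")) embedding$pcs else embedding
  if (nrow(pcs) < 3) abort("need at least 3 cells",
                           class = "inktatlas_param_error")
  nn <- min(n_neighbors, nrow(pcs) - 1)
  coords <- withr::with_seed(config$seed, {
    uwot::umap(pcs, n_neighbors = nn, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  })
  colnames(coords) <- c("UMAP1", "UMAP2")
  if (inherits(embedding, "sc_embedding")) {
    embedding$umap <- coords
    embedding
  } else {
    coords
  }
}

#' Run PCA, clustering and UMAP in one call
#'
#' @inheritParams reduce_pca
#' @return A fully populated [sc_embedding].
#' @export
cluster_embed <- function(norm, hvgs, config = pipeline_config()) {
  emb <- reduce_pca(norm, hvgs, config)
  emb <- cluster_snn(emb, config)
  embed_2d(emb, config)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells,
#' used to score cluster recovery against generator truth.
#'
#' @param a,b label vectors of equal length.
#' @return The ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
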