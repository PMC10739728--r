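#' Project query cells onto a reference embedding by correlation kNN
#'
#' For every query cell, the Pearson correlation with every reference cell
#' is computed over the shared reference-HVG set of log-normalized values;
#' the `config$k_project` highest-correlation reference cells are its
#' neighbours. The projected 2-D coordinate is the unweighted mean of the
#' neighbours' UMAP coordinates, and the assigned subpopulation is the
#' majority cluster label among the neighbours (ties broken by highest
#' mean correlation, then lowest label index). Neighbour ranking ties are
#' broken by reference cell index, so the result is deterministic.
#'
#' Genes absent from the query are dropped (not zero-filled); the realized
#' coverage fraction is recorded. Query cells with zero variance over the
#' shared genes cannot be correlated and are flagged unmappable.
#'
#' @param ref_norm reference [sc_norm].
#' @param ref_embedding reference [sc_embedding] with `umap` and `cluster`.
#' @param ref_hvgs reference HVG tibble from [select_hvgs()] (or a
#'   character vector of gene ids).
#' @param query_norm query [sc_norm].
#' @param config a [pipeline_config()].
#' @return A `projection_result`: a tibble with one row per query cell
#'   (barcode, mappable, neighbor indices and correlations as list
#'   columns, proj_x, proj_y, assigned label) carrying the coverage
#'   fraction and reference label universe as attributes.
#' @export
project_cells <- function(ref_norm, ref_embedding, ref_hvgs, query_norm,
                          config = pipeline_config()) {
  stopifnot(inherits(ref_norm, "sc_norm"), inherits(query_norm, "sc_norm"),
            inherits(ref_embedding, "sc_embedding"))
  if (is.null(ref_embedding$umap) || is.null(ref_embedding$cluster)) {
    abort("reference embedding needs UMAP coordinates and cluster labels",
          class = "inktatlas_param_error")
  }
  k <- config$k_project
  if (ncol(ref_norm$mat) < k) abort("fewer reference cells than k_project",
                                    class = "inktatlas_param_error")
  hvg_ids <- if (is.character(ref_hvgs)) ref_hvgs
             else ref_hvgs$gene_id[ref_hvgs$selected]
  shared <- intersect(hvg_ids, query_norm$genes$gene_id)
  coverage <- length(shared) / length(hvg_ids)
  if (coverage < 0.5) {
    abort(sprintf("only %.0f%% of reference HVGs present in query (need >= 50%%)",
                  100 * coverage), class = "inktatlas_param_error")
  }
  R <- ref_norm$mat[match(shared, ref_norm$genes$gene_id), , drop = FALSE]
  Q <- query_norm$mat[match(shared, query_norm$genes$gene_id), , drop = FALSE]
  q_sd <- apply(Q, 2, stats::sd)
  mappable <- unname(q_sd > 0)
  if (any(!mappable)) {
    warn(sprintf("%d query cells have zero variance over shared genes; flagged unmappable",
                 sum(!mappable)))
  }
  C <- suppressWarnings(stats::cor(Q, R))   # query x reference

  labels <- ref_embedding$cluster
  umap <- ref_embedding$umap
  nq <- ncol(Q)
  nb_idx <- vector("list", nq); nb_cor <- vector("list", nq)
  proj <- matrix(NA_real_, nq, 2)
  assigned <- rep(NA_integer_, nq)
  for (i in seq_len(nq)) {
    if (!mappable[i]) next
    cv <- C[i, ]
    ord <- order(-cv, seq_along(cv))      # ties -> lowest reference index
    nn <- ord[seq_len(k)]
    nb_idx[[i]] <- nn
    nb_cor[[i]] <- unname(cv[nn])
    proj[i, ] <- colMeans(umap[nn, , drop = FALSE])
    nl <- labels[nn]
    votes <- table(nl)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mc <- vapply(top, function(l) mean(cv[nn[nl == l]]), numeric(1))
      top <- top[mc == max(mc)]
      top <- top[order(as.integer(top))][1]  # residual tie -> lowest label
    }
    assigned[i] <- as.integer(top)
  }
  out <- tibble(barcode = query_norm$cells$barcode,
                mappable = mappable,
                neighbors = nb_idx, correlations = nb_cor,
                proj_x = proj[, 1], proj_y = proj[, 2],
                assigned = assigned)
  attr(out, "coverage") <- coverage
  attr(out, "ref_labels") <- sort(unique(labels))
  class(out) <- c("projection_result", class(out))
  out
}

#' Per-group mapping ratios over reference subpopulations
#'
#' For each query group (e.g. tissue of origin), the fraction of mapped
#' cells assigned to each reference subpopulation. Every reference label
#' appears in the output (zero fraction when unused) and fractions sum to
#' 1 within a group. Groups whose cells are all unmappable are omitted
#' with a warning.
#'
#' @param result a `projection_result` from [project_cells()].
#' @param group_by per-query-cell grouping vector (default: one group).
#' @return A tibble with group, reference label, n_cells and ratio.
#' @export
mapping_ratio <- function(result, group_by = rep("query", nrow(result))) {
  stopifnot(inherits(result, "projection_result"),
            length(group_by) == nrow(result))
  ref_labels <- attr(result, "ref_labels")
  purrr::map_dfr(unique(group_by), function(g) {
    sub <- result[group_by == g & result$mappable, ]
    if (nrow(sub) == 0) {
      warn(sprintf("group %s has no mappable cells; omitted", g))
      return(NULL)
    }
    counts <- table(factor(sub$assigned, levels = ref_labels))
    tibble(group = g, ref_label = ref_labels,
           n_cells = as.integer(counts),
           ratio = as.numeric(counts) / nrow(sub))
  })
}
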