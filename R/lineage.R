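#' Infer cluster lineages via a constrained minimum spanning tree
#'
#' Cluster centroids are the per-cluster means of the embedding
#' coordinates. An MST (Euclidean centroid distances, deterministic
#' lexicographic tie-break) is built over the non-end clusters; each
#' designated end cluster is then attached by a single edge to its nearest
#' non-end cluster, guaranteeing it is terminal. Lineages are the
#' root-to-leaf paths starting at the start cluster.
#'
#' @param embedding an [sc_embedding] with cluster labels, or a list with
#'   `coords` (cells-by-d matrix) and `cluster`.
#' @param start the start cluster label.
#' @param ends set of end cluster labels (possibly empty).
#' @param space `"umap"` (default) or `"pca"`: which coordinates to use.
#' @return A `lineage_graph` list: `centroids` tibble, `edges` tibble
#'   (from, to, distance), `lineages` (list of ordered label vectors) and
#'   the start/end labels.
#' @export
infer_lineages <- function(embedding, start, ends = integer(0),
                           space = c("umap", "pca")) {
  space <- match.arg(space)
  if (inherits(embedding, "sc_embedding")) {
    coords <- if (space == "umap") embedding$umap else embedding$pcs
    cluster <- embedding$cluster
  } else {
    coords <- embedding$coords
    cluster <- embedding$cluster
  }
  if (is.null(coords) || is.null(cluster)) {
    abort("embedding needs coordinates and cluster labels",
          class = "inktatlas_param_error")
  }
  labels <- sort(unique(cluster))
  if (length(labels) < 2) abort("need at least 2 clusters",
                                class = "inktatlas_param_error")
  if (!start %in% labels || !all(ends %in% labels)) {
    abort("start/end labels must be existing clusters",
          class = "inktatlas_param_error")
  }
  if (start %in% ends) abort("start cluster cannot be an end cluster",
                             class = "inktatlas_param_error")
  centroids <- t(vapply(labels, function(l) {
    colMeans(coords[cluster == l, , drop = FALSE])
  }, numeric(ncol(coords))))
  rownames(centroids) <- as.character(labels)

  core <- setdiff(labels, ends)
  edges <- mst_edges(centroids[as.character(core), , drop = FALSE])
  edges$from <- core[edges$from]
  edges$to <- core[edges$to]
  for (e in ends) {
    d <- sqrt(rowSums((centroids[as.character(core), , drop = FALSE] -
                       matrix(centroids[as.character(e), ],
                              length(core), ncol(centroids),
                              byrow = TRUE))^2))
    j <- which.min(d)
    edges <- rbind(edges, data.frame(from = core[j], to = e,
                                     distance = d[j]))
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(labels)))
  deg <- igraph::degree(g)
  leaves <- names(deg)[deg == 1 & names(deg) != as.character(start)]
  lineages <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(g, from = as.character(start), to = lf)$vpath[[1]]
    labels[match(names(p), as.character(labels))]
  })
  structure(list(
    centroids = tibble(cluster = labels,
                       as_tibble(centroids, .name_repair = ~ paste0("dim", seq_along(.)))),
    edges = as_tibble(edges),
    lineages = lineages,
    start = start, ends = ends,
    centroid_matrix = centroids),
    class = "lineage_graph")
}

# MST over a centroid matrix; returns integer-indexed edges. Candidate
# edges are enumerated in lexicographic order so igraph's MST breaks
# distance ties deterministically.
mst_edges <- function(centroids) {
  n <- nrow(centroids)
  if (n == 1) return(data.frame(from = integer(0), to = integer(0),
                                distance = numeric(0)))
  pairs <- t(utils::combn(n, 2))
  d <- sqrt(rowSums((centroids[pairs[, 1], , drop = FALSE] -
                     centroids[pairs[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$weight <- d
  t <- igraph::mst(g)
  el <- igraph::as_edgelist(t)
  data.frame(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
             distance = igraph::E(t)$weight)
}

#' @exportS3Method base::print
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %d clusters, start %s, %d lineage(s)\n",
              nrow(x$centroids), x$start, length(x$lineages)))
  for (l in x$lineages) cat("  ", paste(l, collapse = " -> "), "\n")
  invisible(x)
}

#' Per-cell pseudotime along inferred lineages
#'
#' Each cell is orthogonally projected onto the piecewise-linear path
#' through its lineage's centroids (the first lineage containing its
#' cluster); pseudotime is the arc length from the start centroid to the
#' projected point, clamped to the path.
#'
#' @param graph a `lineage_graph` from [infer_lineages()].
#' @param embedding the same embedding the graph was built from.
#' @param space coordinates to use, matching the graph's.
#' @return A tibble with barcode (when available), cluster, lineage index
#'   and pseudotime.
#' @export
pseudotime <- function(graph, embedding, space = c("umap", "pca")) {
  space <- match.arg(space)
  if (inherits(embedding, "sc_embedding")) {
    coords <- if (space == "umap") embedding$umap else embedding$pcs
    cluster <- embedding$cluster
    barcodes <- embedding$barcodes
  } else {
    coords <- embedding$coords
    cluster <- embedding$cluster
    barcodes <- embedding$barcode %||% seq_len(nrow(coords))
  }
  cent <- graph$centroid_matrix
  lineage_of <- vapply(cluster, function(cl) {
    hit <- which(vapply(graph$lineages, function(l) cl %in% l, logical(1)))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(lineage_of)) {
    abort("every cell's cluster must lie on at least one lineage",
          class = "inktatlas_param_error")
  }
  pt <- vapply(seq_len(nrow(coords)), function(i) {
    path <- graph$lineages[[lineage_of[i]]]
    pts <- cent[as.character(path), , drop = FALSE]
    project_on_path(coords[i, ], pts)
  }, numeric(1))
  tibble(barcode = barcodes, cluster = cluster,
         lineage = lineage_of, pseudotime = pt)
}

# arc-length position of the closest point on the piecewise-linear path
project_on_path <- function(p, pts) {
  n_seg <- nrow(pts) - 1
  cum <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                   pts[-nrow(pts), , drop = FALSE])^2))))
  best_d <- Inf; best_t <- 0
  for (s in seq_len(n_seg)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else min(max(sum((p - a) * ab) / len2, 0), 1)
    proj <- a + t * ab
    d <- sum((p - proj)^2)
    if (d < best_d) {
      best_d <- d
      best_t <- cum[s] + t * sqrt(len2)
    }
  }
  min(max(best_t, 0), cum[length(cum)])
}
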