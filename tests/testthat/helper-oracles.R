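# Independent oracles used across tests. These deliberately take the naive
# route (double loops, exhaustive enumeration) so they stay independent of
# the package's implementations.

# single-tissue sim params with k equal subpopulations
single_tissue_params <- function(n_subpops = 4, n_cells = 800, seed = 1,
                                 n_markers_per_subpop = 5, ...) {
  spec <- matrix(1 / n_subpops, n_subpops, 1)
  dimnames(spec) <- list(paste0("A", seq_len(n_subpops)), "tissue1")
  sim_params(n_tissues = 1, subpop_spec = spec,
             n_cells_per_tissue = n_cells, seed = seed,
             n_markers_per_subpop = n_markers_per_subpop, ...)
}

# the reference/query design used for projection checks: the reference
# tissue holds a shared subpop U and a tissue-specific subpop S; the query
# tissue holds U only
ref_query_params <- function(seed, marker_log2fc = 4, n_genes = 1000,
                             n_ref = 300, n_query = 200) {
  spec <- cbind(c(0.5, 0.5), c(1, 0))
  dimnames(spec) <- list(c("U", "S"), c("tissue1", "tissue2"))
  sim_params(n_tissues = 2, subpop_spec = spec,
             n_cells_per_tissue = c(n_ref, n_query),
             n_genes = n_genes, marker_log2fc = marker_log2fc,
             seed = seed)
}

# brute-force Pearson kNN: double loop over query/reference cells
brute_knn_pearson <- function(Q, R, k) {
  nq <- ncol(Q); nr <- ncol(R)
  idx <- matrix(NA_integer_, nq, k)
  cors <- matrix(NA_real_, nq, k)
  for (i in seq_len(nq)) {
    cv <- numeric(nr)
    for (j in seq_len(nr)) cv[j] <- stats::cor(Q[, i], R[, j])
    ord <- order(-cv, seq_len(nr))
    idx[i, ] <- ord[seq_len(k)]
    cors[i, ] <- cv[ord[seq_len(k)]]
  }
  list(idx = idx, cors = cors)
}

# exhaustive two-sided rank-sum p-value: loops over every subset of
# positions assigned to group 1 and recomputes ranks from the raw values
enum_ranksum_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  r <- rank(z)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(z) + 1) / 2
  subsets <- utils::combn(length(z), n1)
  stats <- apply(subsets, 2, function(s) sum(r[s]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# exhaustive minimum spanning tree weight over all (K choose 2) edge subsets
brute_mst_weight <- function(centroids) {
  n <- nrow(centroids)
  pairs <- t(utils::combn(n, 2))
  w <- sqrt(rowSums((centroids[pairs[, 1], , drop = FALSE] -
                     centroids[pairs[, 2], , drop = FALSE])^2))
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    # connectivity check via union-find
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1) {
      best <- min(best, sum(w[sel]))
    }
  }
  best
}

# clusters of cells scattered around given 2-D centers
cells_at <- function(centers, n_per = 20, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(stats::rnorm(n_per, centers[i, 1], sd),
            stats::rnorm(n_per, centers[i, 2], sd))
    }))
  })
  list(coords = coords, cluster = rep(seq_len(nrow(centers)) - 1L,
                                      each = n_per))
}

# 1-D latent gradient: three subpopulations ordered along one axis
gradient_embedding <- function(seed, n_per = 60, spacing = 5) {
  withr::with_seed(seed, {
    centers <- cbind(spacing * (0:2), 0)
    coords <- do.call(rbind, lapply(1:3, function(i) {
      cbind(stats::rnorm(n_per, centers[i, 1], 0.5),
            stats::rnorm(n_per, centers[i, 2], 0.5))
    }))
    list(coords = coords, cluster = rep(0:2, each = n_per))
  })
}
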