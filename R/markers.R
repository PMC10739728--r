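#' Two-sided Wilcoxon rank-sum test with an exact small-sample path
#'
#' Midranks handle ties. For group sizes up to `exact_max` the two-sided
#' p-value is computed by exhaustive enumeration of all assignments of the
#' combined midranks to the first group; for larger groups a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max largest per-group size for the exact path (default 8).
#' @return A list with `statistic` (rank sum of `x`) and `p_value`.
#' @export
ranksum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # exact: distribution of the rank sum over all C(n, n1) assignments
    sums <- utils::combn(r, n1, sum)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = w, p_value = p)
}

# log2 fold-change on de-logged means plus pseudocount (the usual
# single-cell convention)
log2fc_delogged <- function(x_in, x_out, pseudocount = 1) {
  m_in <- mean(2^x_in - 1)
  m_out <- mean(2^x_out - 1)
  log2((m_in + pseudocount) / (m_out + pseudocount))
}

rank_genes <- function(mat) t(apply(mat, 1, rank))

# vectorized one-vs-rest rank-sum over all genes; exact path per gene when
# both groups are small
ranksum_by_gene <- function(mat, in_idx, exact_max = 8) {
  n <- ncol(mat); n1 <- length(in_idx); n2 <- n - n1
  r <- rank_genes(mat)
  w <- rowSums(r[, in_idx, drop = FALSE])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- vapply(seq_len(nrow(mat)), function(g) {
      ranksum_test(mat[g, in_idx], mat[g, -in_idx], exact_max)$p_value
    }, numeric(1))
  } else {
    p <- vapply(seq_len(nrow(mat)), function(g) {
      ties <- table(r[g, ])
      sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      z <- (abs(w[g] - mu) - 0.5) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }, numeric(1))
  }
  list(statistic = w, p_value = p)
}

#' Cluster marker genes by one-vs-rest rank-sum testing
#'
#' For each cluster with at least 3 cells, every gene is tested in-cluster
#' versus all other cells with a two-sided Wilcoxon rank-sum test;
#' p-values are Benjamini-Hochberg adjusted across genes within the
#' cluster. Rows are sorted by adjusted p, then decreasing absolute log2
#' fold-change.
#'
#' @param norm an [sc_norm].
#' @param labels per-cell cluster labels.
#' @param pseudocount pseudocount for the fold-change on de-logged means.
#' @return A tibble with cluster, gene_id, mean log-expression in/out,
#'   log2_fc, p_value and p_adj.
#' @export
find_markers <- function(norm, labels, pseudocount = 1) {
  stopifnot(inherits(norm, "sc_norm"), length(labels) == ncol(norm$mat))
  uniq <- sort(unique(labels))
  if (length(uniq) < 2) abort("need at least 2 clusters",
                              class = "inktatlas_param_error")
  purrr::map_dfr(uniq, function(cl) {
    in_idx <- which(labels == cl)
    if (length(in_idx) < 3) {
      warn(sprintf("cluster %s has fewer than 3 cells; skipped", cl))
      return(NULL)
    }
    res <- ranksum_by_gene(norm$mat, in_idx)
    mean_in <- rowMeans(norm$mat[, in_idx, drop = FALSE])
    mean_out <- rowMeans(norm$mat[, -in_idx, drop = FALSE])
    lfc <- vapply(seq_len(nrow(norm$mat)), function(g) {
      log2fc_delogged(norm$mat[g, in_idx], norm$mat[g, -in_idx], pseudocount)
    }, numeric(1))
    tibble(cluster = cl, gene_id = norm$genes$gene_id,
           mean_in = mean_in, mean_out = mean_out, log2_fc = lfc,
           p_value = res$p_value,
           p_adj = stats::p.adjust(res$p_value, method = "BH")) |>
      dplyr::arrange(.data$p_adj, dplyr::desc(abs(.data$log2_fc)))
  })
}

#' Condition-wise differential expression within clusters
#'
#' Within each cluster, cells of the two condition levels are compared per
#' gene with a two-sided rank-sum test. Adjustment follows
#' `config$de_correction`: Bonferroni (`min(1, m * p)` with `m` the number
#' of genes tested) or Benjamini-Hochberg.
#'
#' @param norm an [sc_norm].
#' @param labels per-cell cluster labels.
#' @param condition per-cell condition labels (exactly 2 levels used).
#' @param config a [pipeline_config()].
#' @return A tibble with cluster, gene_id, log2_fc (first level vs
#'   second), p_value and p_adj.
#' @export
condition_de <- function(norm, labels, condition,
                         config = pipeline_config()) {
  stopifnot(inherits(norm, "sc_norm"))
  levs <- sort(unique(condition))
  if (length(levs) != 2) abort("condition must have exactly 2 levels",
                               class = "inktatlas_param_error")
  purrr::map_dfr(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    a <- idx[condition[idx] == levs[1]]
    b <- idx[condition[idx] == levs[2]]
    if (length(a) < 3 || length(b) < 3) {
      warn(sprintf("cluster %s lacks >= 3 cells in each condition; skipped",
                   cl))
      return(NULL)
    }
    sub <- norm$mat[, c(a, b), drop = FALSE]
    res <- ranksum_by_gene(sub, seq_along(a))
    m <- nrow(sub)
    p_adj <- if (config$de_correction == "bonferroni") {
      pmin(1, m * res$p_value)
    } else {
      stats::p.adjust(res$p_value, method = "BH")
    }
    lfc <- vapply(seq_len(m), function(g) {
      log2fc_delogged(norm$mat[g, a], norm$mat[g, b], config$pseudocount)
    }, numeric(1))
    tibble(cluster = cl, gene_id = norm$genes$gene_id, log2_fc = lfc,
           p_value = res$p_value, p_adj = p_adj)
  })
}

#' Gene-set module score with expression-matched controls
#'
#' Scores each cell as the mean log-normalized expression of the gene set
#' minus the mean of a control set drawn from the same average-expression
#' bins: genes are ranked by average expression into `n_bins` bins and,
#' for every set gene, `n_ctrl` control genes are sampled (without
#' replacement, capped at the pool size) from the non-set genes of its
#' bin; when a bin holds no non-set genes the whole bin serves as its own
#' control (so scoring the full gene universe gives exactly zero).
#' Deterministic given `seed`.
#'
#' @param norm an [sc_norm].
#' @param gene_set character vector of gene ids (subset of the genes).
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed RNG seed for the control draw.
#' @return A tibble with barcode and score.
#' @export
module_score <- function(norm, gene_set, n_bins = 25, n_ctrl = 100,
                         seed = 1L) {
  stopifnot(inherits(norm, "sc_norm"))
  if (length(gene_set) == 0) abort("empty gene set",
                                   class = "inktatlas_param_error")
  all_genes <- norm$genes$gene_id
  if (!all(gene_set %in% all_genes)) abort("gene_set contains unknown genes",
                                           class = "inktatlas_param_error")
  if (length(all_genes) < n_bins) abort("fewer genes than bins",
                                        class = "inktatlas_param_error")
  avg <- rowMeans(norm$mat)
  bins <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  set_idx <- match(gene_set, all_genes)
  ctrl_idx <- withr::with_seed(seed, {
    unlist(lapply(unique(bins[set_idx]), function(b) {
      pool <- setdiff(which(bins == b), set_idx)
      if (length(pool) == 0) pool <- which(bins == b)
      n_take <- min(n_ctrl * sum(bins[set_idx] == b), length(pool))
      sort(sample(pool, n_take))
    }))
  })
  score <- colMeans(norm$mat[set_idx, , drop = FALSE]) -
    colMeans(norm$mat[ctrl_idx, , drop = FALSE])
  tibble(barcode = norm$cells$barcode, score = unname(score))
}
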