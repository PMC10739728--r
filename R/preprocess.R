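#' Filter cells by UMI count and mitochondrial fraction
#'
#' Excludes cells with fewer than `min_umi` total UMIs or with more than
#' `max_mito_fraction` of their UMIs mapped to mitochondrial genes. Both
#' thresholds are strict inequalities: a cell with exactly `min_umi` UMIs
#' and exactly `max_mito_fraction` mitochondrial fraction is kept.
#'
#' @param x an [sc_counts].
#' @param config a [pipeline_config()].
#' @return A list with `counts` (the filtered [sc_counts]) and `qc`, a
#'   tibble covering every input cell with columns barcode, total_umi,
#'   mito_fraction, kept and reason.
#' @export
filter_cells <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "sc_counts"))
  totals <- Matrix::colSums(x$counts)
  mito_umi <- Matrix::colSums(x$counts[x$genes$is_mito, , drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito_umi / totals, 0)
  low_umi <- totals < config$min_umi
  high_mito <- mito_frac > config$max_mito_fraction
  kept <- !low_umi & !high_mito
  reason <- dplyr::case_when(
    low_umi & high_mito ~ "low_umi;high_mito",
    low_umi ~ "low_umi",
    high_mito ~ "high_mito",
    TRUE ~ "pass"
  )
  qc <- tibble(barcode = x$cells$barcode,
               total_umi = unname(as.numeric(totals)),
               mito_fraction = unname(mito_frac), kept = unname(kept),
               reason = reason)
  if (!any(kept)) abort("QC filtering removed every cell",
                        class = "inktatlas_empty_result")
  filtered <- sc_counts(x$counts[, kept, drop = FALSE], x$genes,
                        x$cells[kept, , drop = FALSE])
  list(counts = filtered, qc = qc)
}

#' Compute per-cell size factors
#'
#' The default estimator is library-size factors rescaled to unit mean.
#' `method = "deconvolution"` instead uses pool-based deconvolution
#' (scran's summation approach), likewise rescaled to unit mean; on data
#' without strong composition effects the two coincide.
#'
#' @param x an [sc_counts], or a gene-by-cell matrix.
#' @param method `"library"` (default) or `"deconvolution"`.
#' @param ... passed to `scran::calculateSumFactors()` in deconvolution
#'   mode (e.g. `sizes` for small datasets).
#' @return A numeric vector of strictly positive factors with mean 1,
#'   named by barcode when available.
#' @export
compute_size_factors <- function(x, method = c("library", "deconvolution"),
                                 ...) {
  method <- match.arg(method)
  m <- if (inherits(x, "sc_counts")) x$counts else x
  totals <- Matrix::colSums(m)
  if (any(totals <= 0)) {
    abort("cell with zero total counts; run filter_cells() first",
          class = "inktatlas_param_error")
  }
  sf <- if (method == "library") {
    totals / mean(totals)
  } else {
    if (!requireNamespace("scran", quietly = TRUE)) {
      abort("deconvolution mode requires the scran package")
    }
    s <- scran::calculateSumFactors(as.matrix(m), ...)
    s / mean(s)
  }
  if (any(sf <= 0)) abort("non-positive size factor produced")
  names(sf) <- colnames(m)
  sf
}

#' Log2-normalize counts by size factors
#'
#' Computes `log2(count / size_factor + pseudocount)`; with the default
#' pseudocount of 1, zero counts map to 0.
#'
#' @param x an [sc_counts].
#' @param size_factors positive per-cell factors (default: library-size
#'   factors computed from `x`).
#' @param config a [pipeline_config()] providing the pseudocount.
#' @return An [sc_norm].
#' @export
lognormalize <- function(x, size_factors = compute_size_factors(x),
                         config = pipeline_config()) {
  stopifnot(inherits(x, "sc_counts"))
  if (any(size_factors <= 0)) abort("size factors must be positive",
                                    class = "inktatlas_param_error")
  mat <- as.matrix(x$counts)
  mat <- sweep(mat, 2, size_factors, "/")
  mat <- log2(mat + config$pseudocount)
  sc_norm(mat, size_factors, config$pseudocount, x$genes, x$cells)
}

#' Select highly variable genes
#'
#' Models the per-gene total variance of log-normalized expression as a
#' smooth (loess) trend in the per-gene mean; the biological variance is
#' the total minus the trend. The trend-relative residual
#' `(total - trend) / trend` is standardized by a robust, mean-local
#' spread (MAD within average-expression bins), and the one-sided p-value
#' for positive biological variance comes from a moment-matched scaled
#' chi-square null (`d = 2 / spread^2` effective degrees of freedom) —
#' the right-skewed reference a variance statistic calls for.
#' Benjamini-Hochberg FDR values below `config$hvg_fdr` (with positive
#' biological variance) define the selected set.
#'
#' @param norm an [sc_norm].
#' @param config a [pipeline_config()].
#' @param span loess span for the mean-variance trend.
#' @param n_spread_bins average-expression bins for the local residual
#'   spread.
#' @return A tibble with one row per gene: gene_id, mean, total variance,
#'   trend variance, biological variance, p_value, fdr, selected.
#' @export
select_hvgs <- function(norm, config = pipeline_config(), span = 0.3,
                        n_spread_bins = 20) {
  stopifnot(inherits(norm, "sc_norm"))
  m <- norm$mat
  if (nrow(m) < 20) abort("need at least 20 genes to fit the variance trend",
                          class = "inktatlas_param_error")
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (ncol(m) - 1)
  if (diff(range(mu)) < 1e-12) {
    abort("degenerate trend fit: all gene means equal",
          class = "inktatlas_param_error")
  }
  fit <- stats::loess(v ~ mu, span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  trend <- pmax(stats::predict(fit, mu), 1e-8)
  bio <- v - trend
  rel <- bio / trend
  n_bins <- max(min(n_spread_bins, floor(nrow(m) / 50)), 1)
  bin <- dplyr::ntile(rank(mu, ties.method = "first"), n_bins)
  spread <- stats::ave(rel, bin,
                       FUN = function(x) stats::mad(x, center = 0))
  spread <- pmax(spread, 1e-3)
  d <- 2 / spread^2
  p <- stats::pchisq(d * v / trend, d, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  tibble(gene_id = norm$genes$gene_id, mean = mu, total_var = v,
         trend_var = trend, bio_var = bio, p_value = p, fdr = fdr,
         selected = fdr < config$hvg_fdr & bio > 0)
}

#' One-row summary of an HVG table
#'
#' @param x the tibble returned by [select_hvgs()].
#' @param ... unused.
#' @return A tibble with gene counts and the selected fraction.
#' @export
glance_hvgs <- function(x, ...) {
  tibble(n_genes = nrow(x), n_selected = sum(x$selected),
         frac_selected = mean(x$selected),
         median_trend_var = stats::median(x$trend_var))
}
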