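# hand-built count object where per-cell totals and mito content are exact
toy_counts <- function(totals, mito_frac) {
  n <- length(totals)
  mito <- round(totals * mito_frac)
  other <- totals - mito
  m <- rbind(mito, other, deparse.level = 0)
  sc_counts(Matrix::Matrix(m, sparse = TRUE),
            tibble::tibble(gene_id = c("mt-Nd1", "Actb")),
            tibble::tibble(barcode = paste0("c", seq_len(n))))
}

test_that("QC thresholds are strict inequalities exactly as stated", {
  x <- toy_counts(totals = c(999, 1000, 2000, 2000),
                  mito_frac = c(0, 0.10, 0.10, 0.1005))
  res <- filter_cells(x, pipeline_config())
  expect_equal(res$qc$kept, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res$qc$reason, c("low_umi", "pass", "pass", "high_mito"))
  expect_equal(res$counts$cells$barcode, c("c2", "c3"))
  # report covers all input cells and partitions them
  expect_equal(nrow(res$qc), 4)
  expect_equal(sum(res$qc$kept) + sum(!res$qc$kept), 4)
})

test_that("removing every cell is an explicit error", {
  x <- toy_counts(totals = c(10, 20), mito_frac = c(0, 0))
  expect_error(filter_cells(x, pipeline_config()),
               class = "inktatlas_empty_result")
})

test_that("library-size factors have unit mean and known values", {
  x <- toy_counts(totals = c(100, 200, 300), mito_frac = 0)
  expect_equal(compute_size_factors(x), c(c1 = 0.5, c2 = 1, c3 = 1.5))
  y <- toy_counts(totals = c(50, 50, 50, 50), mito_frac = 0)
  expect_equal(unname(compute_size_factors(y)), rep(1, 4))
  z <- toy_counts(totals = c(0, 10), mito_frac = 0)
  expect_error(compute_size_factors(z), class = "inktatlas_param_error")
})

test_that("size factors are invariant to gene permutation and count scaling", {
  p <- single_tissue_params(n_cells = 50, n_genes = 80, seed = 4)
  ds <- simulate_counts(p)
  sf <- compute_size_factors(ds$counts)
  perm <- sample(nrow(ds$counts$counts))
  x2 <- sc_counts(ds$counts$counts[perm, ], ds$counts$genes[perm, ],
                  ds$counts$cells)
  expect_equal(unname(compute_size_factors(x2)), unname(sf))
  x3 <- sc_counts(ds$counts$counts * 3, ds$counts$genes, ds$counts$cells)
  expect_equal(unname(compute_size_factors(x3)), unname(sf))
})

test_that("deconvolution factors match library-size factors on proportional profiles", {
  # cells are scalar multiples of one profile: no composition effect, so
  # the pool-based estimator must coincide with library-size factors
  withr::with_seed(8, {
    profile <- stats::rpois(300, 5) + 1
    scale <- sample(1:6, 120, replace = TRUE)
    m <- outer(profile, scale)     # exact integer multiples of one profile
  })
  x <- sc_counts(Matrix::Matrix(m, sparse = TRUE),
                 tibble::tibble(gene_id = paste0("g", 1:300)),
                 tibble::tibble(barcode = paste0("c", 1:120)))
  lib <- compute_size_factors(x, "library")
  dec <- compute_size_factors(x, "deconvolution", sizes = c(21, 41, 61))
  expect_equal(unname(dec), unname(lib), tolerance = 1e-6)
})

test_that("lognormalize computes log2(count/sf + pseudocount)", {
  m <- Matrix::Matrix(matrix(c(3, 0, 6, 0), 2, 2), sparse = TRUE)
  x <- sc_counts(m, tibble::tibble(gene_id = c("g1", "g2")),
                 tibble::tibble(barcode = c("c1", "c2")))
  norm <- lognormalize(x, size_factors = c(1, 2), config = pipeline_config())
  expect_equal(norm$mat[1, 1], 2)      # log2(3/1 + 1)
  expect_equal(norm$mat[2, 1], 0)      # zero count -> log2(1)
  expect_equal(norm$mat[1, 2], 2)      # log2(6/2 + 1)
})

test_that("lognormalize is strictly monotone and invertible", {
  counts <- 0:50
  sf <- 1.7
  vals <- log2(counts / sf + 1)
  expect_true(all(diff(vals) > 0))
  back <- (2^vals - 1) * sf
  expect_equal(back, counts, tolerance = 1e-12)
})

test_that("HVG selection flags constant genes as non-HVG and needs variation", {
  withr::with_seed(21, {
    m <- matrix(stats::rnorm(100 * 60, sd = 1), 100, 60)
  })
  m[1, ] <- 5                                  # constant gene
  norm <- sc_norm(m, rep(1, 60), 1,
                  tibble::tibble(gene_id = paste0("g", 1:100)),
                  tibble::tibble(barcode = paste0("c", 1:60)))
  hvg <- select_hvgs(norm)
  expect_false(hvg$selected[1])
  expect_lte(hvg$bio_var[1], 0)
  flat <- sc_norm(matrix(1, 30, 10), rep(1, 10), 1,
                  tibble::tibble(gene_id = paste0("g", 1:30)),
                  tibble::tibble(barcode = paste0("c", 1:10)))
  expect_error(select_hvgs(flat), class = "inktatlas_param_error")
})

test_that("a gene with variance far above trend is selected", {
  p <- single_tissue_params(n_subpops = 1, n_cells = 500, n_genes = 500,
                            seed = 31, marker_log2fc = 0,
                            libsize_lognormal_sigma = 0,
                            high_mito_cell_fraction = 0)
  ds <- simulate_counts(p)
  norm <- lognormalize(ds$counts, rep(1, 500))
  # inflate one well-expressed gene's variance ~10x above its peers
  g <- which.max(rowMeans(norm$mat))
  withr::with_seed(1, {
    norm$mat[g, ] <- mean(norm$mat[g, ]) +
      (norm$mat[g, ] - mean(norm$mat[g, ])) * sqrt(10)
  })
  hvg <- select_hvgs(norm)
  expect_true(hvg$selected[g])
})

test_that("HVG raw p-values are calibrated under an all-null simulation", {
  p <- single_tissue_params(n_subpops = 1, n_cells = 500, n_genes = 2000,
                            seed = 1, marker_log2fc = 0,
                            libsize_lognormal_sigma = 0,
                            mito_mean_inflation = 1,
                            high_mito_cell_fraction = 0)
  ds <- simulate_counts(p)
  norm <- lognormalize(ds$counts, rep(1, 500))
  hvg <- select_hvgs(norm)
  rate <- mean(hvg$p_value < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
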