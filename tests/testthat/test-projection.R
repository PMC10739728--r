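make_ref <- function(R, umap, cluster) {
  list(norm = sc_norm(R, rep(1, ncol(R)), 1,
                      tibble::tibble(gene_id = rownames(R)),
                      tibble::tibble(barcode = colnames(R))),
       emb = sc_embedding(pcs = matrix(0, ncol(R), 2), umap = umap,
                          cluster = cluster, barcodes = colnames(R)))
}

make_query <- function(Q) {
  sc_norm(Q, rep(1, ncol(Q)), 1,
          tibble::tibble(gene_id = rownames(Q)),
          tibble::tibble(barcode = colnames(Q)))
}

rand_mat <- function(n_genes, n_cells, prefix, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_cells, 2), n_genes, n_cells)
  })
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0(prefix, seq_len(n_cells)))
  m
}

test_that("a query identical to a reference cell lands exactly on it", {
  R <- rand_mat(40, 10, "r", 1)
  umap <- cbind(1:10, 11:20)
  colnames(umap) <- c("UMAP1", "UMAP2")
  ref <- make_ref(R, umap, cluster = rep(0:1, each = 5))
  Q <- R[, 4, drop = FALSE]
  colnames(Q) <- "q1"
  res <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q),
                       pipeline_config(k_project = 1))
  expect_equal(res$neighbors[[1]], 4L)
  expect_equal(res$correlations[[1]], 1)
  expect_equal(c(res$proj_x, res$proj_y), unname(umap[4, ]))
  expect_equal(res$assigned, 0L)
})

test_that("two equally correlated neighbours average their coordinates", {
  # reference cells 1 and 2 are identical, so both correlate equally with
  # a matching query; their coordinates (0,0) and (2,2) average to (1,1)
  R <- rand_mat(30, 5, "r", 2)
  R[, 2] <- R[, 1]
  umap <- rbind(c(0, 0), c(2, 2), c(9, 9), c(9, 9), c(9, 9))
  ref <- make_ref(R, umap, cluster = c(0L, 0L, 1L, 1L, 1L))
  Q <- R[, 1, drop = FALSE] + 0    # identical profile
  colnames(Q) <- "q1"
  res <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q),
                       pipeline_config(k_project = 2))
  expect_setequal(res$neighbors[[1]], c(1L, 2L))
  expect_equal(c(res$proj_x, res$proj_y), c(1, 1))
})

test_that("neighbour sets and correlations match the brute-force Pearson oracle", {
  R <- rand_mat(60, 30, "r", 3)
  Q <- rand_mat(60, 10, "q", 4)
  ref <- make_ref(R, cbind(stats::rnorm(30), stats::rnorm(30)),
                  cluster = rep(0:2, each = 10))
  res <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q),
                       pipeline_config(k_project = 5))
  oracle <- brute_knn_pearson(Q, R, k = 5)
  for (i in 1:10) {
    expect_equal(res$neighbors[[i]], oracle$idx[i, ])
    expect_equal(res$correlations[[i]], oracle$cors[i, ], tolerance = 1e-10)
    expect_true(all(abs(res$correlations[[i]]) <= 1))
    # projected coordinate equals the mean of the oracle neighbours
    expect_equal(c(res$proj_x[i], res$proj_y[i]),
                 unname(colMeans(ref$emb$umap[oracle$idx[i, ], ])),
                 tolerance = 1e-10)
  }
})

test_that("projection is invariant to per-cell affine transforms of the query", {
  R <- rand_mat(50, 20, "r", 5)
  Q <- rand_mat(50, 8, "q", 6)
  ref <- make_ref(R, cbind(1:20, 21:40), cluster = rep(0:1, each = 10))
  cfg <- pipeline_config(k_project = 3)
  res1 <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q), cfg)
  Q2 <- sweep(sweep(Q, 2, stats::runif(8, 0.5, 2), "*"), 2,
              stats::rnorm(8), "+")
  res2 <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q2), cfg)
  expect_equal(res1$neighbors, res2$neighbors)
  expect_equal(res1$assigned, res2$assigned)
  expect_equal(res1$proj_x, res2$proj_x, tolerance = 1e-10)
})

test_that("zero-variance query cells are flagged unmappable", {
  R <- rand_mat(40, 12, "r", 7)
  ref <- make_ref(R, cbind(1:12, 1:12), cluster = rep(0:1, each = 6))
  Q <- rand_mat(40, 3, "q", 8)
  Q[, 2] <- 5
  expect_warning(
    res <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q),
                         pipeline_config(k_project = 3)),
    "unmappable")
  expect_equal(res$mappable, c(TRUE, FALSE, TRUE))
  ratios <- mapping_ratio(res)
  expect_equal(sum(ratios$n_cells), 2)
})

test_that("insufficient gene overlap is an error", {
  R <- rand_mat(40, 10, "r", 9)
  ref <- make_ref(R, cbind(1:10, 1:10), cluster = rep(0:1, each = 5))
  Q <- rand_mat(40, 4, "q", 10)
  rownames(Q) <- paste0("other", 1:40)
  rownames(Q)[1:10] <- paste0("g", 1:10)     # 25% coverage only
  expect_error(project_cells(ref$norm, ref$emb, rownames(R), make_query(Q),
                             pipeline_config(k_project = 3)),
               class = "inktatlas_param_error")
})

test_that("mapping ratios sum to one and match hand counts", {
  R <- rand_mat(30, 10, "r", 11)
  ref <- make_ref(R, cbind(1:10, 1:10), cluster = rep(c(0L, 3L), each = 5))
  # build queries identical to chosen reference cells -> known assignment
  Q <- R[, c(1, 2, 3, 6, 7, 1, 2, 3, 6, 7), drop = FALSE]
  colnames(Q) <- paste0("q", 1:10)
  res <- project_cells(ref$norm, ref$emb, rownames(R), make_query(Q),
                       pipeline_config(k_project = 1))
  ratios <- mapping_ratio(res)
  expect_equal(ratios$ratio[ratios$ref_label == 0], 0.6)
  expect_equal(ratios$ratio[ratios$ref_label == 3], 0.4)
  expect_equal(sum(ratios$ratio), 1)
})

test_that("query tissue lacking the tissue-specific subpop maps to the shared one", {
  hits_s <- numeric(0); hits_u <- numeric(0)
  for (s in 1:2) {
    p <- ref_query_params(seed = s)
    ds <- simulate_counts(p)
    res <- filter_cells(ds$counts)
    norm <- lognormalize(res$counts)
    is_ref <- norm$cells$tissue == "tissue1"
    ref <- subset_norm(norm, is_ref); qry <- subset_norm(norm, !is_ref)
    cfg <- pipeline_config(seed = s)
    hvg <- select_hvgs(ref, cfg)
    emb <- cluster_embed(ref, hvg, cfg)
    truth <- ds$truth$cells$subpop[match(ref$cells$barcode,
                                         ds$truth$cells$barcode)]
    tab <- table(emb$cluster, truth)
    s_cl <- as.integer(rownames(tab)[which.max(tab[, "S"])])
    u_cl <- as.integer(rownames(tab)[which.max(tab[, "U"])])
    proj <- project_cells(ref, emb, hvg, qry, cfg)
    ratios <- mapping_ratio(proj)
    hits_s <- c(hits_s, ratios$ratio[ratios$ref_label == s_cl])
    hits_u <- c(hits_u, ratios$ratio[ratios$ref_label == u_cl])
  }
  expect_true(all(hits_s < 0.10))
  expect_true(all(hits_u > 0.80))
})
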