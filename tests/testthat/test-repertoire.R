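contig_row <- function(barcode, chain, v, j, cdr3, umis = 5,
                       productive = TRUE, high_confidence = TRUE) {
  tibble::tibble(barcode = barcode, is_cell = TRUE,
                 high_confidence = high_confidence, chain = chain,
                 v_gene = v, j_gene = j, cdr3 = cdr3,
                 productive = productive, umis = umis)
}

test_that("contig filtering keeps productive AND high-confidence only", {
  recs <- dplyr::bind_rows(
    contig_row("c1", "TRA", "TRAV11", "TRAJ18", "CVV", productive = TRUE,
               high_confidence = FALSE),
    contig_row("c2", "TRB", "TRBV1", "TRBJ1-1", "CAS", productive = FALSE),
    contig_row("c3", "TRB", "TRBV1", "TRBJ1-1", "CAS"))
  kept <- filter_contigs(recs)
  expect_equal(kept$barcode, "c3")
  expect_equal(nrow(filter_contigs(recs[0, ])), 0)
})

test_that("clonotype calling groups identical keys and separates mutants", {
  recs <- dplyr::bind_rows(
    contig_row("c1", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c1", "TRB", "TRBV1", "TRBJ1-1", "CASSLF"),
    contig_row("c2", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c2", "TRB", "TRBV1", "TRBJ1-1", "CASSLF"),
    contig_row("c3", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c3", "TRB", "TRBV1", "TRBJ1-1", "CASSRF"),  # one residue
    contig_row("c4", "TRB", "TRBV1", "TRBJ1-1", "CASSLF"))  # no alpha
  tab <- call_clonotypes(recs, paste0("c", 1:4))
  expect_equal(tab$clonotype_id[1], tab$clonotype_id[2])
  expect_false(tab$clonotype_id[3] == tab$clonotype_id[1])
  expect_true(is.na(tab$clonotype_id[4]))
})

test_that("per-chain contig selection prefers UMIs then lexicographic CDR3", {
  recs <- dplyr::bind_rows(
    contig_row("c1", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c1", "TRB", "TRBV1", "TRBJ1-1", "CASSB", umis = 5),
    contig_row("c1", "TRB", "TRBV2", "TRBJ1-1", "CASSA", umis = 3),
    contig_row("c2", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c2", "TRB", "TRBV9", "TRBJ1-1", "CASSZ", umis = 4),
    contig_row("c2", "TRB", "TRBV3", "TRBJ1-1", "CASSC", umis = 4))
  tab <- call_clonotypes(recs, c("c1", "c2"))
  expect_equal(tab$cdr3_beta[1], "CASSB")   # higher UMI wins
  expect_equal(tab$cdr3_beta[2], "CASSC")   # UMI tie -> smaller CDR3
  expect_warning(call_clonotypes(recs, "c1"), "dropped")
})

test_that("normalized Shannon diversity matches direct evaluation", {
  expect_equal(diversity_normalized_shannon(c(10, 10, 10, 10)), 1.0)
  expect_equal(diversity_normalized_shannon(7), 0.0)
  direct <- -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2)
  expect_equal(diversity_normalized_shannon(c(9, 1)), direct,
               tolerance = 1e-12)
  expect_equal(round(diversity_normalized_shannon(c(9, 1)), 4), 0.469)
  expect_error(diversity_normalized_shannon(numeric(0)),
               class = "inktatlas_param_error")
})

test_that("diversity is invariant to permutation and rescaling", {
  withr::with_seed(23, counts <- sample(1:50, 12))
  h <- diversity_normalized_shannon(counts)
  expect_equal(diversity_normalized_shannon(rev(counts)), h)
  expect_equal(diversity_normalized_shannon(counts * 7), h)
  expect_gte(h, 0); expect_lte(h, 1)
})

test_that("overlap counts, Jaccard and composition follow set arithmetic", {
  # group X has clones {k1,k2}, group Y has {k2,k3}
  recs <- dplyr::bind_rows(
    contig_row(c("x1", "x2", "y1", "y2"), "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("x1", "TRB", "TRBV1", "TRBJ1-1", "CASSA"),
    contig_row("x2", "TRB", "TRBV1", "TRBJ1-1", "CASSB"),
    contig_row("y1", "TRB", "TRBV1", "TRBJ1-1", "CASSB"),
    contig_row("y2", "TRB", "TRBV1", "TRBJ1-1", "CASSC"))
  tab <- call_clonotypes(recs, c("x1", "x2", "y1", "y2"))
  ov <- clonotype_overlap(tab, c("X", "X", "Y", "Y"))
  xy <- dplyr::filter(ov$pairs, group_a == "X", group_b == "Y")
  expect_equal(xy$shared, 1L)
  expect_equal(xy$jaccard, 1 / 3)
  diag <- dplyr::filter(ov$pairs, group_a == group_b)
  expect_true(all(diag$jaccard == 1))
  # symmetry
  yx <- dplyr::filter(ov$pairs, group_a == "Y", group_b == "X")
  expect_equal(yx$shared, xy$shared)
  expect_equal(yx$jaccard, xy$jaccard)
  # shared-clone composition names the overlapping clonotype in both groups
  expect_equal(sort(unique(ov$shared_clones$group)), c("X", "Y"))
  expect_equal(nrow(ov$shared_clones), 2)
})

test_that("engineered shared clones are recovered exactly by overlap", {
  p <- single_tissue_params(n_cells = 600, n_genes = 50, seed = 29,
                            shared_clone_spec = list(list("A1", "A2", 3)),
                            fraction_nonproductive = 0,
                            fraction_low_confidence = 0)
  ds <- simulate_dataset(p)
  tab <- call_clonotypes(filter_contigs(ds$contigs),
                         ds$truth$cells$barcode)
  groups <- ds$truth$cells$subpop
  ov <- clonotype_overlap(tab, groups)
  a12 <- dplyr::filter(ov$pairs, group_a == "A1", group_b == "A2")
  expect_equal(a12$shared, 3L)
  # Jaccard consistent with realized clone-set sizes
  k1 <- length(unique(tab$clonotype_key[groups == "A1" & !is.na(tab$clonotype_key)]))
  k2 <- length(unique(tab$clonotype_key[groups == "A2" & !is.na(tab$clonotype_key)]))
  expect_equal(a12$jaccard, 3 / (k1 + k2 - 3))
})

test_that("clonotype equality is an equivalence relation on random keys", {
  withr::with_seed(31, {
    fields <- function(n) replicate(n, paste(sample(LETTERS, 3), collapse = ""))
    n <- 40
    keys <- tibble::tibble(
      v_a = sample(fields(3), n, TRUE), j_a = sample(fields(2), n, TRUE),
      c_a = sample(fields(4), n, TRUE), v_b = sample(fields(3), n, TRUE),
      j_b = sample(fields(2), n, TRUE), c_b = sample(fields(4), n, TRUE))
  })
  recs <- dplyr::bind_rows(
    contig_row(paste0("c", 1:n), "TRA", keys$v_a, keys$j_a, keys$c_a),
    contig_row(paste0("c", 1:n), "TRB", keys$v_b, keys$j_b, keys$c_b))
  tab <- call_clonotypes(recs, paste0("c", 1:n))
  key_str <- paste(keys$v_a, keys$j_a, keys$c_a, keys$v_b, keys$j_b, keys$c_b)
  # same id <=> same key
  expect_equal(outer(tab$clonotype_id, tab$clonotype_id, "=="),
               outer(key_str, key_str, "=="), ignore_attr = TRUE)
})

test_that("spectratype histogram, modal length and frequency matrix are exact", {
  recs <- dplyr::bind_rows(
    contig_row(c("c1", "c2", "c3"), "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c1", "TRB", "TRBV1", "TRBJ1-1", "CA"),
    contig_row("c2", "TRB", "TRBV1", "TRBJ1-1", "CG"),
    contig_row("c3", "TRB", "TRBV1", "TRBJ1-1", "CASSF"))
  tab <- call_clonotypes(recs, c("c1", "c2", "c3"))
  spec <- cdr3_spectratype(tab)
  # lengths 2,2,5 -> modal 2 (most prevalent)
  expect_equal(spec$modal_length, 2)
  expect_equal(spec$lengths$n_cells[spec$lengths$length == 2], 2L)
  expect_equal(spec$freq_matrix["C", 1], 1.0)
  expect_equal(spec$freq_matrix["A", 2], 0.5)
  expect_equal(spec$freq_matrix["G", 2], 0.5)
  expect_equal(unname(colSums(spec$freq_matrix)), rep(1, 2))

  # single sequence -> one-hot columns; length tie -> shorter length
  one <- call_clonotypes(dplyr::bind_rows(
    contig_row("c1", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("c1", "TRB", "TRBV1", "TRBJ1-1", "CASSF")), "c1")
  sp1 <- cdr3_spectratype(one)
  expect_equal(sp1$modal_length, 5)
  expect_equal(unname(colSums(sp1$freq_matrix == 1)), rep(1, 5))
})

test_that("private clones never increase Jaccard", {
  base <- dplyr::bind_rows(
    contig_row(c("a1", "b1"), "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("a1", "TRB", "TRBV1", "TRBJ1-1", "CASSA"),
    contig_row("b1", "TRB", "TRBV1", "TRBJ1-1", "CASSA"))
  tab1 <- call_clonotypes(base, c("a1", "b1"))
  j1 <- dplyr::filter(clonotype_overlap(tab1, c("A", "B"))$pairs,
                      group_a == "A", group_b == "B")$jaccard
  extra <- dplyr::bind_rows(base,
    contig_row("a2", "TRA", "TRAV11", "TRAJ18", "CVVGD"),
    contig_row("a2", "TRB", "TRBV9", "TRBJ1-1", "CASSZ"))
  tab2 <- call_clonotypes(extra, c("a1", "b1", "a2"))
  j2 <- dplyr::filter(clonotype_overlap(tab2, c("A", "B", "A"))$pairs,
                      group_a == "A", group_b == "B")$jaccard
  expect_lte(j2, j1)
})
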