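#' Filter contigs to productive, high-confidence records
#'
#' @param contigs a tibble of contig records (see [read_contigs_csv()]).
#' @return The rows with `productive` and `high_confidence` both true.
#' @export
filter_contigs <- function(contigs) {
  dplyr::filter(contigs, .data$productive, .data$high_confidence)
}

#' Call paired-chain clonotypes
#'
#' Per cell, one alpha (TRA) and one beta (TRB) contig is selected — the
#' highest-UMI contig per chain, ties broken by lexicographically smallest
#' CDR3 — and cells sharing the same V/J composition and identical CDR3
#' sequences on both chains receive the same clonotype id. Cells lacking
#' either chain are left unassigned. Records whose barcode is not in
#' `cell_barcodes` are dropped with a warning.
#'
#' @param contigs filtered contig records (see [filter_contigs()]).
#' @param cell_barcodes the barcodes of the cells under analysis.
#' @return A tibble with one row per cell: barcode, the six key fields
#'   (v_alpha, j_alpha, cdr3_alpha, v_beta, j_beta, cdr3_beta), the
#'   concatenated clonotype key and an integer clonotype_id (NA when
#'   unassigned).
#' @export
call_clonotypes <- function(contigs, cell_barcodes) {
  unknown <- !contigs$barcode %in% cell_barcodes
  if (any(unknown)) {
    warn(sprintf("%d contigs with barcodes outside the cell set dropped",
                 sum(unknown)))
    contigs <- contigs[!unknown, , drop = FALSE]
  }
  best <- contigs |>
    dplyr::filter(.data$chain %in% c("TRA", "TRB")) |>
    dplyr::group_by(.data$barcode, .data$chain) |>
    dplyr::arrange(dplyr::desc(.data$umis), .data$cdr3, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  wide <- best |>
    dplyr::select("barcode", "chain", "v_gene", "j_gene", "cdr3") |>
    tidyr::pivot_wider(names_from = "chain",
                       values_from = c("v_gene", "j_gene", "cdr3"))
  for (col in c("v_gene_TRA", "j_gene_TRA", "cdr3_TRA",
                "v_gene_TRB", "j_gene_TRB", "cdr3_TRB")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }
  out <- tibble(barcode = cell_barcodes) |>
    dplyr::left_join(wide, by = "barcode") |>
    dplyr::rename(v_alpha = "v_gene_TRA", j_alpha = "j_gene_TRA",
                  cdr3_alpha = "cdr3_TRA", v_beta = "v_gene_TRB",
                  j_beta = "j_gene_TRB", cdr3_beta = "cdr3_TRB")
  paired <- !is.na(out$v_alpha) & !is.na(out$v_beta)
  key <- ifelse(paired,
                paste(out$v_alpha, out$j_alpha, out$cdr3_alpha,
                      out$v_beta, out$j_beta, out$cdr3_beta, sep = "|"),
                NA_character_)
  uniq <- sort(unique(key[!is.na(key)]))
  out$clonotype_key <- key
  out$clonotype_id <- match(key, uniq)
  out
}

#' Normalized Shannon (Pielou) diversity of clone sizes
#'
#' `H_norm = (-sum p_i ln p_i) / ln(S)` with `p_i` the clone frequencies
#' and `S` the number of clonotypes; a single-clone repertoire returns 0
#' by convention. Invariant under permutation and rescaling of the
#' counts.
#'
#' @param clone_counts positive integer vector of cells per clonotype.
#' @return A value in `[0, 1]`.
#' @export
diversity_normalized_shannon <- function(clone_counts) {
  if (length(clone_counts) == 0) abort("empty clone count vector",
                                       class = "inktatlas_param_error")
  if (any(clone_counts <= 0)) abort("clone counts must be positive",
                                    class = "inktatlas_param_error")
  s <- length(clone_counts)
  if (s == 1) return(0)
  p <- clone_counts / sum(clone_counts)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Per-group repertoire diversity
#'
#' @param clonotypes tibble from [call_clonotypes()].
#' @param groups per-cell group labels aligned with `clonotypes`.
#' @return A tibble with group, n_cells (assigned), richness and
#'   normalized Shannon diversity.
#' @export
repertoire_diversity <- function(clonotypes, groups) {
  stopifnot(length(groups) == nrow(clonotypes))
  tibble(group = groups, key = clonotypes$clonotype_key) |>
    dplyr::filter(!is.na(.data$key)) |>
    dplyr::count(.data$group, .data$key) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_cells = sum(.data$n), richness = dplyr::n(),
                     diversity = diversity_normalized_shannon(.data$n))
}

#' Clonotype overlap between groups
#'
#' For every pair of groups: the number of shared clonotypes and the
#' Jaccard index over the groups' clonotype sets; plus, for every
#' clonotype present in more than one group, its per-group cell counts.
#'
#' @param clonotypes tibble from [call_clonotypes()].
#' @param groups per-cell group labels.
#' @return A list with `pairs` (group_a, group_b, shared, jaccard — the
#'   full symmetric matrix in long form, unit diagonal) and `shared_clones`
#'   (clonotype_key, group, n_cells for multi-group clonotypes).
#' @export
clonotype_overlap <- function(clonotypes, groups) {
  stopifnot(length(groups) == nrow(clonotypes))
  df <- tibble(group = groups, key = clonotypes$clonotype_key) |>
    dplyr::filter(!is.na(.data$key))
  counts <- dplyr::count(df, .data$group, .data$key, name = "n_cells")
  present <- sort(unique(counts$group))
  dropped <- setdiff(unique(groups), present)
  if (length(dropped)) {
    warn(paste("groups with no assigned cells excluded:",
               paste(dropped, collapse = ", ")))
  }
  if (length(present) < 2) abort("need at least 2 groups with assigned cells",
                                 class = "inktatlas_param_error")
  sets <- split(counts$key, counts$group)
  pairs <- tidyr::expand_grid(group_a = present, group_b = present) |>
    dplyr::mutate(
      shared = purrr::map2_int(.data$group_a, .data$group_b, function(a, b) {
        length(intersect(sets[[a]], sets[[b]]))
      }),
      jaccard = purrr::map2_dbl(.data$group_a, .data$group_b, function(a, b) {
        length(intersect(sets[[a]], sets[[b]])) /
          length(union(sets[[a]], sets[[b]]))
      }))
  multi <- counts |>
    dplyr::group_by(.data$key) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::rename(clonotype_key = "key")
  list(pairs = pairs, shared_clones = multi)
}

#' CDR3beta spectratype and positional amino-acid frequencies
#'
#' Over the assigned cells of one group: the CDR3beta length histogram,
#' the modal length (ties broken toward the shorter length), and the
#' 20-by-L positional amino-acid frequency matrix over the cells whose
#' CDR3beta has the modal length (columns sum to 1). The matrix is the
#' numeric content of a sequence logo.
#'
#' @param clonotypes tibble from [call_clonotypes()].
#' @param cells optional logical/index subset of rows (a group).
#' @return A list with `lengths` (tibble length/n_cells/fraction),
#'   `modal_length` and `freq_matrix`.
#' @export
cdr3_spectratype <- function(clonotypes, cells = NULL) {
  sub <- if (is.null(cells)) clonotypes else clonotypes[cells, , drop = FALSE]
  cdr3 <- sub$cdr3_beta[!is.na(sub$clonotype_key)]
  if (length(cdr3) == 0) abort("no assigned cells in group",
                               class = "inktatlas_param_error")
  len <- nchar(cdr3)
  hist <- tibble(length = sort(unique(len))) |>
    dplyr::mutate(n_cells = vapply(.data$length, function(L) sum(len == L),
                                   integer(1)),
                  fraction = .data$n_cells / length(len))
  modal <- min(hist$length[hist$n_cells == max(hist$n_cells)])
  seqs <- cdr3[len == modal]
  aa <- aa_alphabet()
  freq <- vapply(seq_len(modal), function(pos) {
    ch <- substr(seqs, pos, pos)
    tab <- table(factor(ch, levels = aa))
    as.numeric(tab) / length(ch)
  }, numeric(length(aa)))
  rownames(freq) <- aa
  colnames(freq) <- paste0("pos", seq_len(modal))
  list(lengths = hist, modal_length = modal, freq_matrix = freq)
}
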