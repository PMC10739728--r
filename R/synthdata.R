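#' Simulation parameters for the synthetic multi-tissue dataset
#'
#' Defines the generative model used by [simulate_counts()] and
#' [simulate_tcr()]: several tissues share some subpopulations and possess
#' tissue-specific ones; counts are negative binomial with per-subpopulation
#' marker programs; library sizes are log-normal; a designated cell fraction
#' carries inflated mitochondrial expression; every cell carries an invariant
#' TCR alpha chain and a beta chain drawn from per-subpopulation clone pools
#' with Dirichlet-distributed frequencies, optionally with engineered clone
#' sharing between subpopulations.
#'
#' The defaults emulate a two-tissue design in which tissue 1 (e.g. adipose)
#' harbours a tissue-specific subpopulation `A2` absent from tissue 2, while
#' `A1`, `A3` and `A4` are shared in different proportions — the structure
#' needed to exercise reference projection and mapping ratios.
#'
#' @param n_tissues number of tissues.
#' @param subpop_spec matrix of per-tissue subpopulation proportions with one
#'   column per tissue and named rows (subpopulation ids); each column sums
#'   to 1. A tissue-specific subpopulation has nonzero proportion in exactly
#'   one tissue.
#' @param n_cells_per_tissue cells simulated per tissue (recycled).
#' @param n_genes total genes, including mitochondrial genes.
#' @param n_markers_per_subpop marker genes upregulated in each subpopulation.
#' @param marker_log2fc log2 fold-change of marker genes in their
#'   subpopulation (>= 0; 0 switches the effect off).
#' @param baseline_mean_shape,baseline_mean_scale gamma parameters for
#'   per-gene baseline means.
#' @param nb_dispersion negative binomial dispersion phi in
#'   `var = mu + mu^2 * phi` (> 0).
#' @param libsize_lognormal_sigma sigma of the log-normal per-cell library
#'   size factor (>= 0).
#' @param mito_gene_fraction fraction of genes that are mitochondrial.
#' @param mito_mean_inflation multiplier (>= 1) applied to mitochondrial gene
#'   means in high-mito cells.
#' @param high_mito_cell_fraction fraction of cells designated high-mito.
#' @param condition_probs named probabilities of diet/condition labels
#'   assigned per cell (default a single `"NCD"` condition).
#' @param clone_dirichlet_alpha Dirichlet concentration for clone
#'   frequencies (> 0; small values give clonal expansion).
#' @param n_clones_per_subpop clones in each subpopulation's pool.
#' @param shared_clone_spec list of `list(a, b, n)` entries injecting `n`
#'   clones shared between subpopulations `a` and `b`.
#' @param fraction_nonproductive fraction of contigs flagged non-productive.
#' @param fraction_low_confidence fraction flagged low-confidence.
#' @param seed master seed; all random streams derive from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_tissues = 2,
                       subpop_spec = default_subpop_spec(n_tissues),
                       n_cells_per_tissue = 600,
                       n_genes = 2000,
                       n_markers_per_subpop = 50,
                       marker_log2fc = 2,
                       baseline_mean_shape = 0.5,
                       baseline_mean_scale = 2,
                       nb_dispersion = 0.4,
                       libsize_lognormal_sigma = 0.3,
                       mito_gene_fraction = 0.03,
                       mito_mean_inflation = 4,
                       high_mito_cell_fraction = 0.05,
                       condition_probs = c(NCD = 1),
                       clone_dirichlet_alpha = 0.8,
                       n_clones_per_subpop = 30,
                       shared_clone_spec = list(),
                       fraction_nonproductive = 0.05,
                       fraction_low_confidence = 0.05,
                       seed = 1L) {
  p <- list(n_tissues = as.integer(n_tissues),
            subpop_spec = as.matrix(subpop_spec),
            n_cells_per_tissue = rep_len(as.integer(n_cells_per_tissue),
                                         as.integer(n_tissues)),
            n_genes = as.integer(n_genes),
            n_markers_per_subpop = as.integer(n_markers_per_subpop),
            marker_log2fc = marker_log2fc,
            baseline_mean_shape = baseline_mean_shape,
            baseline_mean_scale = baseline_mean_scale,
            nb_dispersion = nb_dispersion,
            libsize_lognormal_sigma = libsize_lognormal_sigma,
            mito_gene_fraction = mito_gene_fraction,
            mito_mean_inflation = mito_mean_inflation,
            high_mito_cell_fraction = high_mito_cell_fraction,
            condition_probs = condition_probs,
            clone_dirichlet_alpha = clone_dirichlet_alpha,
            n_clones_per_subpop = as.integer(n_clones_per_subpop),
            shared_clone_spec = shared_clone_spec,
            fraction_nonproductive = fraction_nonproductive,
            fraction_low_confidence = fraction_low_confidence,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' @rdname sim_params
#' @export
default_subpop_spec <- function(n_tissues = 2) {
  if (n_tissues == 1) {
    m <- matrix(c(0.4, 0.3, 0.2, 0.1), ncol = 1)
  } else {
    m <- cbind(c(0.4, 0.3, 0.2, 0.1),
               c(0.6, 0.0, 0.3, 0.1))
    if (n_tissues > 2) m <- cbind(m, matrix(rep(c(0.6, 0, 0.3, 0.1),
                                                n_tissues - 2), ncol = n_tissues - 2))
  }
  dimnames(m) <- list(paste0("A", 1:4), paste0("tissue", seq_len(n_tissues)))
  m
}

validate_sim_params <- function(p) {
  if (p$n_tissues < 1 || any(p$n_cells_per_tissue < 1) || p$n_genes < 1 ||
      p$n_clones_per_subpop < 1) {
    abort("all counts must be positive", class = "inktatlas_param_error")
  }
  if (ncol(p$subpop_spec) != p$n_tissues) {
    abort("subpop_spec must have one column per tissue",
          class = "inktatlas_param_error")
  }
  if (any(p$subpop_spec < 0) ||
      any(abs(colSums(p$subpop_spec) - 1) > 1e-8)) {
    abort("per-tissue subpopulation proportions must be nonnegative and sum to 1",
          class = "inktatlas_param_error")
  }
  if (is.null(rownames(p$subpop_spec))) {
    abort("subpop_spec rows must be named with subpopulation ids",
          class = "inktatlas_param_error")
  }
  if (p$marker_log2fc < 0 || p$nb_dispersion <= 0 ||
      p$libsize_lognormal_sigma < 0 || p$mito_mean_inflation < 1 ||
      p$clone_dirichlet_alpha <= 0) {
    abort("parameter out of range", class = "inktatlas_param_error")
  }
  for (fr in c("mito_gene_fraction", "high_mito_cell_fraction",
               "fraction_nonproductive", "fraction_low_confidence")) {
    if (p[[fr]] < 0 || p[[fr]] > 1) {
      abort(paste(fr, "must lie in [0, 1]"), class = "inktatlas_param_error")
    }
  }
  invisible(p)
}

# One independent sub-seed per logical component, derived from the master
# seed, so e.g. adding cells does not perturb the TCR draws.
derive_seeds <- function(seed) {
  withr::with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 4L)
  })
  stats::setNames(s, c("genes", "counts", "libsize", "tcr"))
}

#' Simulate a ground-truth single-cell count matrix
#'
#' Draws a gene-by-cell UMI matrix from the negative binomial model
#' `NB(mean = baseline * 2^(marker_log2fc * is_marker) * libsize_factor,
#' var = mean + mean^2 * phi)`. Mitochondrial gene means are additionally
#' multiplied by `mito_mean_inflation` in a designated high-mito cell
#' fraction. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return A list with `counts` (an [sc_counts]) and `truth`, a list holding
#'   per-cell truth (`cells`: barcode, tissue, subpop, condition, high_mito,
#'   libsize factor), per-gene truth (`genes`: gene_id, is_mito, marker_of,
#'   baseline mean) and the `params` used.
#' @export
simulate_counts <- function(params) {
  validate_sim_params(params)
  seeds <- derive_seeds(params$seed)
  subpops <- rownames(params$subpop_spec)

  n_mito <- round(params$n_genes * params$mito_gene_fraction)
  gene_id <- c(sprintf("mt-Mito%03d", seq_len(n_mito)),
               sprintf("Gene%05d", seq_len(params$n_genes - n_mito)))
  is_mito <- startsWith(gene_id, "mt-")

  # marker blocks drawn from the non-mito genes, disjoint across subpops
  non_mito <- which(!is_mito)
  need <- params$n_markers_per_subpop * length(subpops)
  if (need > length(non_mito)) {
    abort("not enough non-mito genes for the requested marker blocks",
          class = "inktatlas_param_error")
  }
  marker_of <- rep(NA_character_, params$n_genes)
  withr::with_seed(seeds[["genes"]], {
    marker_idx <- sample(non_mito, need)
    baseline <- stats::rgamma(params$n_genes, shape = params$baseline_mean_shape,
                              scale = params$baseline_mean_scale)
  })
  baseline <- pmax(baseline, 1e-3)
  marker_of[marker_idx] <- rep(subpops, each = params$n_markers_per_subpop)

  # deterministic per-tissue subpop allocation (largest-remainder rounding)
  cell_tissue <- rep(colnames(params$subpop_spec), params$n_cells_per_tissue)
  cell_subpop <- unlist(lapply(seq_len(params$n_tissues), function(t) {
    n <- params$n_cells_per_tissue[t]
    prop <- params$subpop_spec[, t]
    base <- floor(prop * n)
    rem <- n - sum(base)
    if (rem > 0) {
      frac_order <- order(prop * n - base, decreasing = TRUE)
      base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1L
    }
    rep(subpops, base)
  }))
  n_cells <- length(cell_subpop)
  barcode <- unlist(lapply(seq_len(params$n_tissues), function(t) {
    sprintf("CELL-%s-%04d", colnames(params$subpop_spec)[t],
            seq_len(params$n_cells_per_tissue[t]))
  }))

  withr::with_seed(seeds[["libsize"]], {
    lib <- stats::rlnorm(n_cells, meanlog = 0,
                         sdlog = params$libsize_lognormal_sigma)
    lib <- lib / mean(lib)
    high_mito <- stats::runif(n_cells) < params$high_mito_cell_fraction
    condition <- sample(names(params$condition_probs), n_cells,
                        replace = TRUE, prob = params$condition_probs)
  })

  # per-subpop mean profiles, then NB draws cell by cell
  lfc_mult <- 2^params$marker_log2fc
  profile <- vapply(subpops, function(sp) {
    m <- baseline
    m[!is.na(marker_of) & marker_of == sp] <-
      m[!is.na(marker_of) & marker_of == sp] * lfc_mult
    m
  }, numeric(params$n_genes))

  size <- 1 / params$nb_dispersion
  withr::with_seed(seeds[["counts"]], {
    cols <- lapply(seq_len(n_cells), function(j) {
      mu <- profile[, cell_subpop[j]] * lib[j]
      if (high_mito[j]) mu[is_mito] <- mu[is_mito] * params$mito_mean_inflation
      stats::rnbinom(params$n_genes, size = size, mu = mu)
    })
  })
  counts <- methods::as(do.call(cbind, cols), "CsparseMatrix")

  genes <- tibble(gene_id = gene_id, is_mito = is_mito,
                  marker_of = marker_of, baseline_mean = baseline)
  cells <- tibble(barcode = barcode, tissue = cell_tissue,
                  subpop = cell_subpop, condition = condition,
                  high_mito = high_mito, libsize_factor = lib)
  obj <- sc_counts(counts, genes, cells[, c("barcode", "tissue", "condition")])
  truth <- structure(list(cells = cells, genes = genes, params = params),
                     class = "sim_truth")
  list(counts = obj, truth = truth)
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# The semi-invariant mouse iNKT alpha chain (Valpha14-Jalpha18).
invariant_alpha <- function() {
  list(v_gene = "TRAV11", j_gene = "TRAJ18", cdr3 = "CVVGDRGSALGRLHF")
}

random_cdr3b <- function(n) {
  lens <- sample(11:17, n, replace = TRUE)
  vapply(lens, function(L) {
    paste0("CASS", paste(sample(aa_alphabet(), L - 5, replace = TRUE),
                         collapse = ""), "F")
  }, character(1))
}

#' Simulate paired TCR contigs with engineered clonotype sharing
#'
#' Every cell receives one alpha contig with the fixed invariant
#' (TRAV11, TRAJ18, CVVGDRGSALGRLHF) chain and one beta contig drawn from its
#' subpopulation's clone pool with Dirichlet-distributed clone frequencies.
#' Clones named in `shared_clone_spec` are injected into both subpopulations'
#' pools; all other clones are globally unique. A configurable fraction of
#' contigs is flagged non-productive or low-confidence. Deterministic given
#' `params$seed`.
#'
#' @param truth the `truth` component returned by [simulate_counts()].
#' @param params the same [sim_params()] object.
#' @return A tibble of contig records in the 10x
#'   `filtered_contig_annotations.csv` dialect (barcode, is_cell,
#'   high_confidence, chain, v_gene, j_gene, cdr3, productive, umis), with
#'   attributes `cell_clones` (tibble: barcode, subpop, clone_id and the beta
#'   key fields) and `clone_pools` (tibble of the per-subpopulation clone
#'   pools with realized frequencies).
#' @export
simulate_tcr <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"))
  seeds <- derive_seeds(params$seed)
  subpops <- rownames(params$subpop_spec)
  trbv <- c("TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV29", "TRBV19",
            "TRBV1", "TRBV5", "TRBV12-1", "TRBV2", "TRBV17")
  trbj <- c("TRBJ2-1", "TRBJ2-5", "TRBJ2-7", "TRBJ1-1", "TRBJ1-4")

  withr::with_seed(seeds[["tcr"]], {
    # shared clones first, then unique fillers per subpop
    shared <- dplyr::bind_rows(
      tibble(subpop_a = character(0), subpop_b = character(0),
             v_gene = character(0), j_gene = character(0),
             cdr3 = character(0)),
      purrr::map_dfr(params$shared_clone_spec, function(s) {
        tibble(subpop_a = s[[1]], subpop_b = s[[2]],
               v_gene = sample(trbv, s[[3]], replace = TRUE),
               j_gene = sample(trbj, s[[3]], replace = TRUE),
               cdr3 = random_cdr3b(s[[3]]))
      }))
    # regenerate any colliding CDR3 so pools stay disjoint except by design
    all_cdr3 <- shared$cdr3
    pools <- purrr::map_dfr(subpops, function(sp) {
      sh <- dplyr::filter(shared, .data$subpop_a == sp | .data$subpop_b == sp)
      n_new <- max(params$n_clones_per_subpop - nrow(sh), 0L)
      cdr3_new <- character(0)
      while (length(cdr3_new) < n_new) {
        cand <- random_cdr3b(n_new - length(cdr3_new))
        cand <- setdiff(unique(cand), all_cdr3)
        cdr3_new <- c(cdr3_new, cand)
        all_cdr3 <<- c(all_cdr3, cand)
      }
      dplyr::bind_rows(
        tibble(subpop = sp, v_gene = sh$v_gene, j_gene = sh$j_gene,
               cdr3 = sh$cdr3, shared = TRUE),
        tibble(subpop = sp, v_gene = sample(trbv, n_new, replace = TRUE),
               j_gene = sample(trbj, n_new, replace = TRUE),
               cdr3 = cdr3_new, shared = FALSE)
      )
    })
    pools$clone_id <- paste(pools$v_gene, pools$j_gene, pools$cdr3, sep = "_")

    # Dirichlet clone frequencies per subpop, then per-cell clone draws
    cells <- truth$cells
    cell_rows <- purrr::map_dfr(subpops, function(sp) {
      pool <- dplyr::filter(pools, .data$subpop == sp)
      idx <- which(cells$subpop == sp)
      g <- stats::rgamma(nrow(pool), shape = params$clone_dirichlet_alpha)
      freq <- g / sum(g)
      draw <- sample.int(nrow(pool), length(idx), replace = TRUE, prob = freq)
      # engineered shared clones must be realized in both named subpops:
      # give any unrealized one a cell, taken from the largest clone
      for (k in which(pool$shared)) {
        if (length(idx) > 0 && !k %in% draw) {
          donor <- which(draw == as.integer(names(which.max(table(draw)))))[1]
          draw[donor] <- k
        }
      }
      tibble(barcode = cells$barcode[idx], subpop = sp,
             clone_id = pool$clone_id[draw],
             v_gene = pool$v_gene[draw], j_gene = pool$j_gene[draw],
             cdr3 = pool$cdr3[draw])
    })
    cell_rows <- cell_rows[match(cells$barcode, cell_rows$barcode), ]

    inv <- invariant_alpha()
    n <- nrow(cell_rows)
    contigs <- dplyr::bind_rows(
      tibble(barcode = cell_rows$barcode, chain = "TRA",
             v_gene = inv$v_gene, j_gene = inv$j_gene, cdr3 = inv$cdr3),
      tibble(barcode = cell_rows$barcode, chain = "TRB",
             v_gene = cell_rows$v_gene, j_gene = cell_rows$j_gene,
             cdr3 = cell_rows$cdr3)
    )
    contigs$is_cell <- TRUE
    contigs$umis <- stats::rpois(nrow(contigs), 4) + 1L
    contigs$productive <- stats::runif(nrow(contigs)) >=
      params$fraction_nonproductive
    contigs$high_confidence <- stats::runif(nrow(contigs)) >=
      params$fraction_low_confidence
  })
  contigs <- contigs[, c("barcode", "is_cell", "high_confidence", "chain",
                         "v_gene", "j_gene", "cdr3", "productive", "umis")]
  attr(contigs, "cell_clones") <- cell_rows
  attr(contigs, "clone_pools") <- pools
  contigs
}

#' Simulate the full dataset (counts + TCR) in one call
#'
#' @param params a [sim_params()] object.
#' @return A list with `counts`, `truth` (with per-cell `clone_id` joined
#'   into `truth$cells`) and `contigs`.
#' @export
simulate_dataset <- function(params) {
  sim <- simulate_counts(params)
  contigs <- simulate_tcr(sim$truth, params)
  cc <- attr(contigs, "cell_clones")
  sim$truth$cells <- dplyr::left_join(
    sim$truth$cells, cc[, c("barcode", "clone_id")], by = "barcode")
  list(counts = sim$counts, truth = sim$truth, contigs = contigs)
}
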