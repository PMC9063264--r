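# Integration metrics (kNN acceptance test, inverse Simpson index) on a
# common PCA embedding, plus truth-based recovery metrics for simulated
# data. Both integration scores live on a 0-1 scale where 0 means no
# mixing of the grouping labels and 1 means full mixing.

#' PCA embedding of a count matrix
#'
#' Log-normalizes, selects the most variable genes and projects cells onto
#' the top principal components. Components are sign-fixed so the
#' embedding is deterministic given the seed.
#'
#' @param view a [CountMatrix()].
#' @param n_pcs number of components (default 20).
#' @param n_hvg number of variable genes (default 2000).
#' @param seed RNG seed.
#' @return cells x `n_pcs` coordinate matrix.
#' @export
embed <- function(view, n_pcs = 20L, n_hvg = 2000L, seed = 1L) {
  validate_count_matrix(view)
  if (length(view$barcodes) <= n_pcs)
    stop_integrity("need more than n_pcs cells to embed")
  ln <- lognorm(view$counts)
  hv <- top_variable_genes(ln, n_hvg)
  pca_embed(ln[hv, , drop = FALSE], n_pcs = n_pcs, seed = seed)
}

#' Local inverse Simpson index of label mixing
#'
#' For each cell, the proportions of each label among its k nearest
#' neighbours (self excluded) give an inverse Simpson index
#' `1 / sum(p^2)`: the effective number of labels in the neighbourhood.
#' The mean index is normalized to \[0, 1\] as `(mean - 1) / (B - 1)` with
#' B the number of labels; a single label scores 0 by convention.
#'
#' @param labels per-cell grouping labels.
#' @param coords embedding coordinates (cells x dims).
#' @param k neighbourhood size (default 30).
#' @param correction use the unbiased small-sample Simpson estimator
#'   `sum(n_b * (n_b - 1)) / (k * (k - 1))` (default). The plain plug-in
#'   `sum(p_b^2)` underestimates diversity at small k, so randomly mixed
#'   batches would score visibly below 1.
#' @return List: `per_cell` indices, `score` normalized to \[0, 1\].
#' @export
lisi <- function(labels, coords, k = 30L, correction = TRUE) {
  stopifnot(length(labels) == nrow(coords), k < nrow(coords))
  labels <- as.character(labels)
  lv <- unique(labels)
  B <- length(lv)
  idx <- knn_index(coords, k)
  kk <- ncol(idx)
  if (kk < 10) correction <- FALSE   # too few neighbours to debias
  lab_mat <- matrix(labels[idx], nrow = nrow(idx))
  isi <- vapply(seq_len(nrow(idx)), function(i) {
    n_b <- tabulate(factor(lab_mat[i, ], levels = lv), nbins = B)
    s <- if (correction && kk > 1) {
      sum(n_b * (n_b - 1)) / (kk * (kk - 1))
    } else {
      sum((n_b / kk)^2)
    }
    1 / max(s, 1 / kk^2)
  }, numeric(1))
  score <- if (B == 1) 0 else (mean(isi) - 1) / (B - 1)
  list(per_cell = isi, score = min(max(score, 0), 1))
}

#' kNN acceptance test of batch mixing
#'
#' For randomly chosen cells, a chi-squared goodness-of-fit test compares
#' the batch composition of the cell's k-neighbourhood against the global
#' batch proportions; the score is the fraction of neighbourhoods NOT
#' rejected at level `alpha`. Well-mixed batches score about `1 - alpha`;
#' fully separated batches score about 0. One batch scores 1 by
#' convention. Batches whose expected neighbourhood count falls below 1
#' are merged into the smallest adequate batch, with a warning.
#'
#' @param labels per-cell batch labels.
#' @param coords embedding coordinates.
#' @param k neighbourhood size (default 50, minimum 10).
#' @param alpha rejection level (default 0.05).
#' @param n_test number of tested cells (default 500).
#' @param seed RNG seed for the test sample.
#' @param null `"empirical"` (default) calibrates the chi-squared critical
#'   value on multinomial draws from the global proportions, so the test
#'   holds its size exactly at finite k; `"asymptotic"` uses the
#'   chi-squared distribution directly.
#' @param n_null multinomial draws for the empirical null.
#' @return Acceptance rate in \[0, 1\].
#' @export
kbet_lite <- function(labels, coords, k = 50L, alpha = 0.05, n_test = 500L,
                      seed = 1L, null = c("empirical", "asymptotic"),
                      n_null = 5000L) {
  stopifnot(length(labels) == nrow(coords), k >= 10)
  null <- match.arg(null)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) return(1)
  k <- min(k, nrow(coords) - 1L)
  prop <- table(labels) / length(labels)
  while (any(prop * k < 1) && length(prop) > 2) {
    warning("merging smallest batches: expected neighbourhood count < 1")
    ord <- order(prop)
    labels[labels == names(prop)[ord[1]]] <- names(prop)[ord[2]]
    prop <- table(labels) / length(labels)
  }
  lv <- names(prop)
  set.seed(seed)
  test_cells <- sample.int(nrow(coords), min(n_test, nrow(coords)))
  idx <- knn_index(coords, k)
  expected <- as.numeric(prop) * k
  stat_of <- function(obs) sum((obs - expected)^2 / expected)
  crit <- if (null == "empirical") {
    null_draws <- rmultinom(n_null, k, as.numeric(prop))
    null_stats <- colSums((null_draws - expected)^2 / expected)
    # smallest threshold whose null rejection rate does not exceed alpha
    unname(quantile(null_stats, 1 - alpha, type = 1))
  } else {
    stats::qchisq(1 - alpha, df = length(lv) - 1)
  }
  rejected <- vapply(test_cells, function(i) {
    obs <- tabulate(factor(labels[idx[i, ]], levels = lv), nbins = length(lv))
    stat_of(obs) > crit
  }, logical(1))
  mean(!rejected)
}

#' Integration scores per group
#'
#' Computes the kNN acceptance score and the normalized inverse Simpson
#' score of `batch` mixing within each level of `group` (for example per
#' cell type), reporting only groups with at least `min_cells` cells.
#'
#' @param batch per-cell batch labels (the variable whose mixing is
#'   scored).
#' @param group per-cell grouping labels (`NULL` scores the whole dataset
#'   as one group).
#' @param coords embedding coordinates.
#' @param min_cells smallest group reported (default 100).
#' @param k_kbet,k_lisi neighbourhood sizes.
#' @param alpha,n_test,seed passed to [kbet_lite()].
#' @return `data.frame`: `group`, `n_cells`, `kbet_score`, `lisi_score`.
#' @export
integration_scores <- function(batch, group = NULL, coords, min_cells = 100L,
                               k_kbet = 50L, k_lisi = 30L, alpha = 0.05,
                               n_test = 500L, seed = 1L) {
  if (is.null(group)) group <- rep("all", length(batch))
  stopifnot(length(batch) == nrow(coords), length(group) == length(batch))
  out <- list()
  for (g in unique(group)) {
    in_g <- which(group == g)
    if (length(in_g) < min_cells) next
    co <- coords[in_g, , drop = FALSE]
    kb <- kbet_lite(batch[in_g], co, k = min(k_kbet, length(in_g) - 1L),
                    alpha = alpha, n_test = n_test, seed = seed)
    li <- lisi(batch[in_g], co, k = min(k_lisi, length(in_g) - 1L))$score
    out[[g]] <- data.frame(group = g, n_cells = length(in_g),
                           kbet_score = kb, lisi_score = li,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group = character(), n_cells = integer(),
                      kbet_score = numeric(), lisi_score = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Truth-based recovery metrics for a simulated run
#'
#' Scores pipeline output against simulator ground truth. Any subset of
#' the inputs may be given; only the corresponding metrics are computed.
#'
#' @param truth the simulator truth table.
#' @param calls a `SpeciesCall` (species accuracy, doublet
#'   precision/recall).
#' @param doublet_scores a `DoubletScore` on one species' retained cells
#'   (intrasample doublet recall at the expected-rate cutoff).
#' @param rho_estimate named per-cell contamination estimates, compared to
#'   the true ambient fraction (median absolute error).
#' @param trap_removed named list with `before`/`after` total trap-gene
#'   counts (removal fraction).
#' @return Named list of metrics.
#' @export
truth_metrics <- function(truth, calls = NULL, doublet_scores = NULL,
                          rho_estimate = NULL, trap_removed = NULL) {
  out <- list()
  if (!is.null(calls)) {
    idx <- match(calls$barcode, truth$barcode)
    tt <- truth[idx, ]
    # accuracy over singlets that received a species decision; barcodes the
    # prefilter discarded were filtered, not misclassified
    decided <- !calls$label %in% c("empty_like", "low_quality", "pending")
    singlet <- tt$class %in% c("human_singlet", "mouse_singlet") & decided
    out$species_accuracy <- mean(calls$label[singlet] == tt$species[singlet])
    is_cross <- tt$class == "cross_doublet"
    called_cross <- calls$label == "cross_doublet"
    out$cross_doublet_recall <- if (any(is_cross))
      mean(called_cross[is_cross]) else NA_real_
    out$cross_doublet_precision <- if (any(called_cross))
      mean(is_cross[called_cross]) else NA_real_
  }
  if (!is.null(doublet_scores)) {
    idx <- match(doublet_scores$barcode, truth$barcode)
    is_dbl <- truth$class[idx] == "intrasample_doublet"
    out$intrasample_doublet_recall <- if (any(is_dbl))
      mean(doublet_scores$call[is_dbl]) else NA_real_
  }
  if (!is.null(rho_estimate)) {
    idx <- match(names(rho_estimate), truth$barcode)
    out$rho_median_abs_error <- median(abs(rho_estimate - truth$rho[idx]))
  }
  if (!is.null(trap_removed)) {
    out$trap_removal_fraction <-
      1 - trap_removed$after / max(trap_removed$before, 1)
  }
  out
}
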