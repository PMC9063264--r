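# Step 3: restrict each species-matching view to its called barcodes,
# apply per-sample quality control, and detect intrasample doublets with
# an artificial-doublet kNN scorer.

#' Select species-matching barcodes on a realigned view
#'
#' @param view a single-species [CountMatrix()].
#' @param calls a `SpeciesCall`.
#' @return The view restricted to barcodes called as its species.
#' @export
select_matching_barcodes <- function(view, calls) {
  validate_count_matrix(view)
  if (!view$view %in% c("human", "mouse"))
    stop_integrity("select_matching_barcodes needs a single-species view")
  keep <- calls$barcode[calls$label == view$view]
  if (length(keep) == 0)
    stop_integrity("no barcode was called ", view$view)
  subset_barcodes(view, keep)
}

#' Per-sample quality filter
#'
#' Each sample is filtered on its own distribution, so samples of
#' different depth or quality are not judged by one global bar: cells are
#' kept when log10 total reads and log10 expressed genes are no more than
#' `mad_multiplier` scaled MADs below the sample median, and the
#' mitochondrial percentage no more than `mad_multiplier` MADs above it.
#' A zero MAD (identical values) is floored so a cell exactly at the
#' median is never removed. Samples with fewer than `min_sample_cells`
#' cells are filtered on thresholds pooled over all cells, with a warning.
#'
#' @param view a single-species [CountMatrix()] of retained cells.
#' @param sample_id per-barcode sample identity, aligned with the view's
#'   barcodes (from pooled-sample deconvolution or, in simulations, truth).
#' @param mad_multiplier MADs from the median (default 3).
#' @param min_sample_cells minimum sample size for per-sample thresholds.
#' @return List: `keep` (barcodes passing), `stats` per barcode,
#'   `thresholds` per sample.
#' @export
per_sample_qc <- function(view, sample_id, mad_multiplier = 3,
                          min_sample_cells = 10L) {
  validate_count_matrix(view)
  stopifnot(length(sample_id) == length(view$barcodes))
  total <- Matrix::colSums(view$counts)
  genes <- Matrix::colSums(view$counts > 0)
  mito <- Matrix::colSums(view$counts[view$features$is_mito, , drop = FALSE])
  stats <- data.frame(barcode = view$barcodes, sample_id = sample_id,
                      log_total = log10(total + 1), log_genes = log10(genes + 1),
                      mito_pct = ifelse(total > 0, 100 * mito / total, 0),
                      stringsAsFactors = FALSE)
  thr_for <- function(d) {
    data.frame(
      min_log_total = median(d$log_total) - mad_multiplier * mad_floor(d$log_total),
      min_log_genes = median(d$log_genes) - mad_multiplier * mad_floor(d$log_genes),
      max_mito_pct = median(d$mito_pct) + mad_multiplier * mad_floor(d$mito_pct))
  }
  global <- thr_for(stats)
  thresholds <- list()
  keep <- logical(nrow(stats))
  for (s in unique(sample_id)) {
    in_s <- sample_id == s
    if (sum(in_s) < min_sample_cells) {
      warning("sample ", s, " has fewer than ", min_sample_cells,
              " cells; using global thresholds")
      thr <- global
    } else thr <- thr_for(stats[in_s, ])
    thresholds[[s]] <- thr
    keep[in_s] <- stats$log_total[in_s] >= thr$min_log_total &
      stats$log_genes[in_s] >= thr$min_log_genes &
      stats$mito_pct[in_s] <= thr$max_mito_pct
  }
  list(keep = stats$barcode[keep], stats = stats,
       thresholds = do.call(rbind, thresholds))
}

#' Score intrasample doublets with artificial doublets
#'
#' Implements the artificial-nearest-neighbour scheme: `pN * n` artificial
#' doublets are formed by pooling two random cells' libraries (after
#' depth normalization this is the average of their expression profiles),
#' real and artificial cells are embedded together by PCA, and each real
#' cell's doublet score `pANN` is the fraction of artificial doublets
#' among its `k` nearest neighbours. The
#' `expected_rate * n` highest-scoring cells are called doublets.
#'
#' @param view a single-species [CountMatrix()] of QC-passing cells.
#' @param expected_rate expected intrasample doublet fraction.
#' @param pN artificial doublets generated per real cell (default 0.25).
#' @param k neighbourhood size (default 30).
#' @param n_pcs embedding dimensions (default 20).
#' @param seed RNG seed.
#' @return `data.frame` of class `DoubletScore`: `barcode`, `pANN` in
#'   \[0, 1\], `call`.
#' @export
doublet_finder_lite <- function(view, expected_rate, pN = 0.25, k = 30L,
                                n_pcs = 20L, seed = 1L) {
  validate_count_matrix(view)
  n <- length(view$barcodes)
  if (n < 50) stop_integrity("need >= 50 cells for doublet scoring")
  stopifnot(expected_rate >= 0, expected_rate <= 1, pN > 0)
  set.seed(seed)
  n_art <- max(1L, round(pN * n))
  pa <- sample.int(n, n_art, replace = TRUE)
  pb <- sample.int(n, n_art, replace = TRUE)
  # an artificial doublet is the pooled raw library of two cells,
  # normalized afterwards like any droplet
  art_counts <- view$counts[, pa, drop = FALSE] + view$counts[, pb, drop = FALSE]
  merged <- lognorm(cbind(view$counts, art_counts))
  hv <- top_variable_genes(merged[, seq_len(n), drop = FALSE], 2000L)
  merged <- merged[hv, , drop = FALSE]
  emb <- pca_embed(merged, n_pcs = n_pcs, seed = seed)
  idx <- knn_index(emb, k)[seq_len(n), , drop = FALSE]
  pann <- rowMeans(idx > n)
  n_call <- floor(expected_rate * n)
  call <- rep(FALSE, n)
  if (n_call >= 1) {
    call[order(pann, decreasing = TRUE)[seq_len(n_call)]] <- TRUE
  } else if (expected_rate > 0) {
    warning("expected_rate * n < 1; no doublets called")
  }
  structure(data.frame(barcode = view$barcodes, pANN = pann, call = call,
                       stringsAsFactors = FALSE),
            class = c("DoubletScore", "data.frame"))
}
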