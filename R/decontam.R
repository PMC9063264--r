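# Step 4: ambient RNA contamination estimation and removal.
#
# Contamination is decomposed per cell into a cross-species component
# (other-species reads visible in the combined view - information only a
# combined-reference alignment has) and a same-species component estimated
# from soup-dominated genes within the matching view, then inflated by a
# fixed stringency bump before subtraction.

#' Cross-species contamination fraction per cell
#'
#' In the combined view, reads on the other species' genes inside a called
#' cell can only be ambient (or misaligned ambient); their share of the
#' cell's reads estimates the other-species ambient fraction directly.
#'
#' @param combined combined-view [CountMatrix()].
#' @param barcodes retained cell barcodes.
#' @param species species each barcode was called as (single value or
#'   vector).
#' @return Named numeric vector, other-species read fraction per barcode.
#' @export
estimate_rho_cross <- function(combined, barcodes, species) {
  validate_count_matrix(combined)
  if (combined$view != "combined")
    stop_integrity("estimate_rho_cross needs the combined view")
  species <- rep_len(species, length(barcodes))
  xs <- subset_barcodes(combined, barcodes)
  tot <- Matrix::colSums(xs$counts)
  if (any(tot == 0)) stop_integrity("barcode(s) with zero total reads")
  h <- Matrix::colSums(xs$counts[xs$features$species == "human", , drop = FALSE])
  other <- ifelse(species == "human", tot - h, h)
  setNames(other / tot, barcodes)
}

#' Same-species contamination fraction per cell
#'
#' For each cluster, an estimation gene set is chosen: genes prominent in
#' the ambient profile (above its `soup_quantile` among genes with ambient
#' signal) that the cluster itself does not meaningfully express - observed
#' cluster mean at most `max(eps_counts, max_contam * meanN * b_g)`, i.e.
#' no more than `max_contam` contamination could explain it. Counts a cell
#' carries on those genes are then pure soup, and
#' `rho = sum(n_g) / (N_cell * sum(b_g))` over the set estimates its
#' contamination fraction. Cells in clusters with fewer than `min_genes`
#' usable genes receive the dataset median.
#'
#' @param view single-species [CountMatrix()] of retained cells.
#' @param clusters per-barcode cluster labels aligned with the view.
#' @param ambient an [estimate_ambient_profile()] result on this view's
#'   gene space (fractions are renormalized to the shared genes).
#' @param soup_quantile ambient-fraction quantile defining prominent soup
#'   genes (default 0.90).
#' @param eps_counts absolute cluster-mean expression floor (default 0.01).
#' @param max_contam largest contamination fraction the gene-set rule may
#'   attribute to soup (default 0.35).
#' @param min_genes minimum usable genes per cluster (default 5).
#' @return Named numeric vector of per-cell fractions in \[0, 1\].
#' @export
estimate_rho_same <- function(view, clusters, ambient, soup_quantile = 0.90,
                              eps_counts = 0.01, max_contam = 0.35,
                              min_genes = 5L) {
  validate_count_matrix(view)
  stopifnot(length(clusters) == length(view$barcodes))
  b <- ambient$fractions[match(view$features$feature_id, names(ambient$fractions))]
  b[is.na(b)] <- 0
  if (sum(b) == 0) stop_integrity("ambient profile is empty on this view's genes")
  b <- b / sum(b)
  N <- Matrix::colSums(view$counts)
  soup_thr <- quantile(b[b > 0], soup_quantile)
  soupy <- which(b >= soup_thr & b > 0)
  rho <- rep(NA_real_, length(N))
  for (cl in unique(clusters)) {
    in_cl <- which(clusters == cl)
    cl_mean <- Matrix::rowMeans(view$counts[soupy, in_cl, drop = FALSE])
    ceiling_soup <- pmax(eps_counts, max_contam * mean(N[in_cl]) * b[soupy])
    G_c <- soupy[cl_mean <= ceiling_soup]
    if (length(G_c) < min_genes) {
      # every prominent soup gene looks expressed: either the cluster is
      # essentially ambient (ratios near a common high value) or soup and
      # expression overlap pathologically; the ratio quantile below is the
      # soup-consistent (conservative) estimate either way
      if (length(soupy) >= min_genes) G_c <- soupy else next
    }
    # soup-only genes share one expression-to-soup ratio (the cluster's
    # contamination level); genes the cluster weakly expresses sit above
    # it. The low quantile of the per-gene ratios is a robust estimate of
    # that level, and the per-cell estimates are calibrated to it so weak
    # expression leaking into G_c cannot bias the cluster upward.
    r_g <- Matrix::rowMeans(view$counts[G_c, in_cl, drop = FALSE]) /
      (mean(N[in_cl]) * b[G_c])
    rho_cluster <- unname(quantile(r_g, 0.10))
    n_g <- Matrix::colSums(view$counts[G_c, in_cl, drop = FALSE])
    raw <- n_g / (pmax(N[in_cl], 1) * sum(b[G_c]))
    scale_f <- if (mean(raw) > 0) rho_cluster / mean(raw) else 1
    rho[in_cl] <- pmin(pmax(raw * scale_f, 0), 1)
  }
  if (anyNA(rho)) {
    med <- median(rho, na.rm = TRUE)
    if (is.na(med)) med <- 0
    rho[is.na(rho)] <- med
  }
  setNames(rho, view$barcodes)
}

#' Total contamination rate with a stringency bump
#'
#' @param rho_cross,rho_same per-cell components.
#' @param bump additional fraction removed for stringency (default 0.05).
#' @param per_species apply the bump to each component instead of once.
#' @return Per-cell total contamination, capped at 1.
#' @export
total_rho <- function(rho_cross, rho_same, bump = 0.05, per_species = FALSE) {
  stopifnot(all(rho_cross >= 0 & rho_cross <= 1),
            all(rho_same >= 0 & rho_same <= 1), bump >= 0, bump <= 1)
  add <- if (per_species) 2 * bump else bump
  pmin(rho_cross + rho_same + add, 1)
}

#' Subtract expected ambient counts from a matching view
#'
#' The expected soup count of gene g in cell c is
#' `rho_c * N_c * b_g`; its ceiling is subtracted and the result clipped
#' at zero, so corrected counts stay non-negative integers and never
#' exceed the originals.
#'
#' @param view single-species [CountMatrix()] of retained cells.
#' @param rho_total per-cell contamination (aligned with barcodes).
#' @param ambient an [estimate_ambient_profile()] result (fractions are
#'   renormalized to this view's genes).
#' @return List: `corrected` [CountMatrix()], `removed_per_cell` counts.
#' @export
remove_ambient <- function(view, rho_total, ambient) {
  validate_count_matrix(view)
  stopifnot(length(rho_total) == length(view$barcodes),
            all(rho_total >= 0 & rho_total <= 1))
  b <- ambient$fractions[match(view$features$feature_id, names(ambient$fractions))]
  b[is.na(b)] <- 0
  if (sum(b) > 0) b <- b / sum(b)
  N <- Matrix::colSums(view$counts)
  m <- as(view$counts, "TsparseMatrix")
  expected <- rho_total[m@j + 1L] * N[m@j + 1L] * b[m@i + 1L]
  newx <- pmax(m@x - ceiling(expected), 0)
  corrected <- Matrix::sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = newx,
                                    dims = dim(m))
  out <- view
  out$counts <- as(corrected, "CsparseMatrix")
  rownames(out$counts) <- view$features$feature_id
  colnames(out$counts) <- view$barcodes
  removed <- N - Matrix::colSums(out$counts)
  list(corrected = out, removed_per_cell = setNames(removed, view$barcodes))
}
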