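# Misalignment audit: compare the species-matching view of a library with
# its combined-reference view over a shared barcode set. Reads lost by a
# gene between the two views, reads appearing on the other species' genes,
# and the increment in excluded exonic multi-mappers together make up the
# combined-reference error.

#' Compare a species-matching view with the combined view
#'
#' For the given barcodes, tallies each gene's reads in the matching
#' reference and in the combined reference, the per-gene read loss, and the
#' total reads assigned to the other species' genes in the combined view.
#'
#' @param matching a single-species [CountMatrix()] (`view` = `"human"` or
#'   `"mouse"`).
#' @param combined the combined-view [CountMatrix()] of the same library.
#' @param barcodes barcodes to audit (must exist in both views); defaults
#'   to all barcodes of the matching view.
#' @return A list of class `MisalignmentReport`:
#' \describe{
#'   \item{per_gene}{`data.frame` per matching-view gene: `matching_count`,
#'     `combined_count`, `read_loss_pct` (percent of matching-reference
#'     reads lost in the combined reference; `NA` when the gene has no
#'     matching reads), `avg_count_per_cell`.}
#'   \item{reads_misaligned_to_other}{total combined-view reads on
#'     other-species genes over these barcodes.}
#'   \item{read_gain}{per other-species gene, the combined-view reads it
#'     received on these barcodes.}
#'   \item{matching_total, combined_total, n_cells, species}{aggregates.}
#' }
#' @export
compare_views <- function(matching, combined, barcodes = matching$barcodes) {
  validate_count_matrix(matching); validate_count_matrix(combined)
  if (!matching$view %in% c("human", "mouse"))
    stop_integrity("`matching` must be a single-species view")
  if (combined$view != "combined")
    stop_integrity("`combined` must be the combined view")
  m <- subset_barcodes(matching, barcodes)
  cb <- subset_barcodes(combined, barcodes)
  sp <- matching$view
  own <- cb$features$species == sp

  matching_count <- Matrix::rowSums(m$counts)
  comb_own <- Matrix::rowSums(cb$counts[own, , drop = FALSE])
  comb_own <- comb_own[match(m$features$feature_id,
                             cb$features$feature_id[own])]
  comb_own[is.na(comb_own)] <- 0
  gain <- Matrix::rowSums(cb$counts[!own, , drop = FALSE])

  per_gene <- data.frame(
    feature_id = m$features$feature_id,
    matching_count = matching_count,
    combined_count = comb_own,
    read_loss_pct = ifelse(matching_count > 0,
                           100 * (matching_count - comb_own) / matching_count, NA),
    avg_count_per_cell = matching_count / length(barcodes),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(per_gene = per_gene,
                 reads_misaligned_to_other = sum(gain),
                 read_gain = setNames(gain, cb$features$feature_id[!own]),
                 matching_total = sum(matching_count),
                 combined_total = sum(comb_own),
                 n_cells = length(barcodes),
                 species = sp),
            class = "MisalignmentReport")
}

#' @export
print.MisalignmentReport <- function(x, ...) {
  cat(sprintf(paste0("MisalignmentReport [%s]: %d cells, %.0f matching reads, ",
                     "%.0f combined reads, %.0f misaligned to other species\n"),
              x$species, x$n_cells, x$matching_total, x$combined_total,
              x$reads_misaligned_to_other))
  invisible(x)
}

#' Combined-reference error rate
#'
#' The error of the combined reference relative to the species-matching
#' reference: reads misaligned to the other species plus the increment in
#' excluded exonic multi-mapping reads, as a fraction of total
#' matching-reference reads.
#'
#' @param reads_misaligned_to_other reads on other-species genes in the
#'   combined view.
#' @param multimap_matching,multimap_combined excluded exonic multi-mapping
#'   read totals under each reference.
#' @param matching_total total reads in the matching reference.
#' @return Error as a fraction.
#' @export
error_rate <- function(reads_misaligned_to_other, multimap_matching,
                       multimap_combined, matching_total) {
  stopifnot(reads_misaligned_to_other >= 0, multimap_matching >= 0,
            multimap_combined >= 0)
  if (matching_total <= 0) stop_integrity("matching_total must be positive")
  (reads_misaligned_to_other +
     multimap_increment(multimap_matching, multimap_combined)) / matching_total
}

#' Increment of excluded multi-mapping reads in the combined reference
#'
#' @param multimap_matching,multimap_combined excluded exonic multi-mapping
#'   read totals under the matching and combined references.
#' @return `max(multimap_combined - multimap_matching, 0)`.
#' @export
multimap_increment <- function(multimap_matching, multimap_combined) {
  stopifnot(multimap_matching >= 0, multimap_combined >= 0)
  max(multimap_combined - multimap_matching, 0)
}

#' Flag misaligned genes
#'
#' A gene is called misaligned when it averages more than `min_avg` reads
#' per cell in the matching reference and its count differs by more than
#' `min_diff` (as a fraction of its matching-reference count) between the
#' two references.
#'
#' @param report a `MisalignmentReport` from [compare_views()].
#' @param n_cells number of cells (defaults to the report's).
#' @param min_avg average-reads-per-cell floor (default 0.1).
#' @param min_diff fractional count-difference threshold (default 0.10).
#' @param direction `"absolute"` flags both loss and gain; `"loss"` flags
#'   loss only.
#' @return Character vector of flagged feature ids.
#' @export
call_misaligned_genes <- function(report, n_cells = report$n_cells,
                                  min_avg = 0.1, min_diff = 0.10,
                                  direction = c("absolute", "loss")) {
  stopifnot(inherits(report, "MisalignmentReport"), n_cells > 0)
  direction <- match.arg(direction)
  pg <- report$per_gene
  diff <- (pg$matching_count - pg$combined_count) / pg$matching_count
  if (direction == "absolute") diff <- abs(diff)
  hit <- pg$matching_count / n_cells > min_avg &
    pg$matching_count > 0 & diff > min_diff
  pg$feature_id[hit & !is.na(hit)]
}

# ledger-derived oracle aggregates for a barcode set; used by the audit
# tests and the acceptance checks
ledger_aggregates <- function(ledger, barcodes, species) {
  l <- ledger[ledger$barcode %in% barcodes, ]
  own <- l$origin_species == species
  list(
    # combined-view reads on other-species genes: own-origin reads that
    # crossed over plus other-origin (ambient/doublet) reads counted
    # correctly on their own genes
    misaligned_to_other = sum(l$n_cross[own]) + sum(l$n_correct[!own]),
    multimap_matching = 0,                  # matching view excludes none
    multimap_combined = sum(l$n_multi),
    # matching view holds all own-origin reads plus other-origin reads that
    # cross-misaligned into this species' gene space
    matching_view_total = sum(l$n_matching[own]) + sum(l$n_cross[!own]))
}
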