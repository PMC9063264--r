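#' @importFrom methods as is new
#' @importFrom stats median mad var cor quantile rbinom rnorm rlnorm rbeta
#'   rgamma rmultinom runif prcomp pchisq kmeans setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

# classed conditions so callers can distinguish malformed files from
# internally inconsistent ones
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("xdeconv_format_error", "error")))
}
stop_integrity <- function(...) {
  stop(errorCondition(paste0(...), class = c("xdeconv_integrity_error", "error")))
}

#' Construct a feature (gene) annotation table
#'
#' The feature table is shared by every view of a library. It records, for
#' each gene, its species of origin, whether it is mitochondrial, its rank
#' along its genome (used for copy-number smoothing) and, where known, the
#' identifier linking a human gene to its mouse homolog.
#'
#' @param feature_id character, unique gene identifiers.
#' @param feature_name character, gene symbols (mitochondrial genes are
#'   recognised by the `MT-` / `mt-` name prefix).
#' @param species character, `"human"` or `"mouse"` per feature.
#' @param is_mito logical or `NULL`; inferred from `feature_name` when `NULL`.
#' @param chromosome character or `NA`.
#' @param genomic_index integer rank of the gene along its own genome
#'   (a permutation within each species); defaults to order of appearance.
#' @param homolog_id optional character; a given id must appear on exactly
#'   one human and one mouse feature.
#' @param mito_genes optional character vector of feature names to flag as
#'   mitochondrial instead of the prefix rule.
#' @return A `data.frame` with the columns above.
#' @export
feature_table <- function(feature_id, feature_name = feature_id, species,
                          is_mito = NULL, chromosome = NA_character_,
                          genomic_index = NULL, homolog_id = NA_character_,
                          mito_genes = NULL) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop_integrity("feature_ids are not unique")
  species <- match.arg(species, c("human", "mouse"), several.ok = TRUE)
  species <- rep_len(species, length(feature_id))
  if (is.null(is_mito)) {
    if (!is.null(mito_genes)) {
      is_mito <- feature_name %in% mito_genes
    } else {
      # strip a combined-reference prefix before testing the name
      nm <- sub("^(GRCh38|GRCh38-3\\.0\\.0|hg19|mm10|mm10-3\\.0\\.0)[_-]", "",
                feature_name)
      is_mito <- startsWith(nm, "MT-") | startsWith(nm, "mt-")
    }
  }
  if (is.null(genomic_index)) {
    genomic_index <- integer(length(feature_id))
    for (s in unique(species)) {
      idx <- species == s
      genomic_index[idx] <- seq_len(sum(idx))
    }
  }
  ft <- data.frame(
    feature_id = feature_id,
    feature_name = as.character(feature_name),
    species = species,
    is_mito = as.logical(is_mito),
    chromosome = as.character(chromosome),
    genomic_index = as.integer(genomic_index),
    homolog_id = as.character(homolog_id),
    stringsAsFactors = FALSE
  )
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  stopifnot(is.data.frame(ft))
  need <- c("feature_id", "feature_name", "species", "is_mito",
            "chromosome", "genomic_index", "homolog_id")
  miss <- setdiff(need, names(ft))
  if (length(miss))
    stop_integrity("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ft$feature_id))
    stop_integrity("feature_ids are not unique")
  if (!all(ft$species %in% c("human", "mouse")))
    stop_integrity("species must be 'human' or 'mouse'")
  hid <- ft$homolog_id[!is.na(ft$homolog_id)]
  if (length(hid)) {
    tab <- table(ft$species[!is.na(ft$homolog_id)], ft$homolog_id[!is.na(ft$homolog_id)])
    if (any(tab > 1) || any(colSums(tab > 0) != 2 & colSums(tab) > 1))
      if (any(tab > 1))
        stop_integrity("a homolog_id appears more than once within a species")
  }
  for (s in unique(ft$species)) {
    gi <- ft$genomic_index[ft$species == s]
    if (!setequal(gi, seq_along(gi)))
      stop_integrity("genomic_index is not a permutation within species ", s)
  }
  invisible(ft)
}

#' Construct a count matrix for one reference view
#'
#' A `CountMatrix` couples a sparse non-negative integer gene-by-barcode
#' matrix with its feature table and the reference view it was aligned to:
#' the combined two-species reference, or a single-species matching
#' reference.
#'
#' @param counts a matrix or `Matrix::dgCMatrix`, features x barcodes,
#'   non-negative integers.
#' @param features a feature table (see [feature_table()]) with one row per
#'   matrix row.
#' @param barcodes character, one per matrix column.
#' @param view `"combined"`, `"human"` or `"mouse"`. Single-species views
#'   may only contain that species' features.
#' @return An object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, features, barcodes, view = c("combined", "human", "mouse")) {
  view <- match.arg(view)
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  obj <- structure(list(counts = counts, features = features,
                        barcodes = as.character(barcodes), view = view),
                   class = "CountMatrix")
  validate_count_matrix(obj)
  rownames(obj$counts) <- features$feature_id
  colnames(obj$counts) <- obj$barcodes
  obj
}

validate_count_matrix <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  validate_feature_table(x$features)
  if (nrow(x$counts) != nrow(x$features))
    stop_integrity("counts rows (", nrow(x$counts), ") != features (", nrow(x$features), ")")
  if (ncol(x$counts) != length(x$barcodes))
    stop_integrity("counts cols (", ncol(x$counts), ") != barcodes (", length(x$barcodes), ")")
  if (length(x$counts@x) && min(x$counts@x) < 0)
    stop_integrity("negative counts")
  if (x$view %in% c("human", "mouse") && !all(x$features$species == x$view))
    stop_integrity("view=", x$view, " but features of the other species are present")
  invisible(x)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s view]: %d features x %d barcodes, %.0f reads\n",
              x$view, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  sp <- table(x$features$species)
  cat("  features:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "),
      sprintf("(%d mito)\n", sum(x$features$is_mito)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

# restrict a CountMatrix to a barcode subset (order preserved as given)
subset_barcodes <- function(x, barcodes) {
  idx <- match(barcodes, x$barcodes)
  if (anyNA(idx))
    stop_integrity("barcode(s) absent from the ", x$view, " view: ",
                   paste(head(barcodes[is.na(idx)], 3), collapse = ", "))
  x$counts <- x$counts[, idx, drop = FALSE]
  x$barcodes <- x$barcodes[idx]
  x
}
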