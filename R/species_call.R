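# Species and cross-species doublet calling on the combined view:
# ambient profile from sub-threshold barcodes, prefilter on expressed
# genes and mitochondrial content, atlas correlation per species,
# correlation cutoffs, rule-based classification, cluster-level minority
# removal and optional copy-number support for tumour samples.
#
# Every label change carries a rule id in `reasons`, so removals are
# auditable barcode by barcode.

#' Estimate the ambient RNA profile from near-empty barcodes
#'
#' Ambient RNA is cell-free RNA that enters droplets and is sequenced
#' alongside the cell's own transcripts. Barcodes with fewer than `cap`
#' total reads are taken as cell-free and summed into a gene fraction
#' vector; the mitochondrial read percentage of the pool is computed per
#' species.
#'
#' @param x a [CountMatrix()] (any view).
#' @param cap barcodes with total reads strictly below this are used
#'   (default 100).
#' @return A list of class `AmbientProfile`: `fractions` (named, sums to
#'   1), `mito_pct` (named per species, 0-100), `n_source_barcodes`.
#' @export
estimate_ambient_profile <- function(x, cap = 100) {
  validate_count_matrix(x)
  tot <- Matrix::colSums(x$counts)
  sub <- tot < cap
  if (!any(sub))
    stop_integrity("no ambient evidence: no barcode has fewer than ", cap, " reads")
  pool <- Matrix::rowSums(x$counts[, sub, drop = FALSE])
  mito_pct <- vapply(c(human = "human", mouse = "mouse"), function(s) {
    own <- x$features$species == s
    stot <- sum(pool[own])
    if (stot == 0) 0 else 100 * sum(pool[own & x$features$is_mito]) / stot
  }, numeric(1))
  structure(list(fractions = setNames(pool / sum(pool), x$features$feature_id),
                 mito_pct = mito_pct,
                 n_source_barcodes = sum(sub)),
            class = "AmbientProfile")
}

#' @export
print.AmbientProfile <- function(x, ...) {
  cat(sprintf("AmbientProfile from %d barcodes; mito%%: human %.2f, mouse %.2f\n",
              x$n_source_barcodes, x$mito_pct[["human"]], x$mito_pct[["mouse"]]))
  invisible(x)
}

new_species_call <- function(barcodes, majority) {
  structure(data.frame(barcode = barcodes, label = "pending",
                       majority = majority, reasons = "",
                       stringsAsFactors = FALSE),
            class = c("SpeciesCall", "data.frame"))
}

set_label <- function(calls, idx, label, reason) {
  calls$label[idx] <- label
  calls$reasons[idx] <- ifelse(nzchar(calls$reasons[idx]),
                               paste(calls$reasons[idx], reason, sep = ";"),
                               reason)
  calls
}

#' Prefilter barcodes on the combined view
#'
#' Barcodes below the ambient read cap are labelled `empty_like`. Among the
#' rest, a barcode is kept only if it expresses at least `min_genes` genes
#' in the human gene set and/or the mouse gene set, and is dropped when its
#' mitochondrial percentage in either species reaches `mito_multiplier`
#' times the ambient pool's mitochondrial percentage for that species (a
#' species is tested only when the barcode has reads in it and the ambient
#' pool shows mitochondrial signal there). Survivors stay `pending`.
#'
#' @param x combined-view [CountMatrix()].
#' @param ambient an [estimate_ambient_profile()] result.
#' @param min_genes expressed-gene threshold per species (default 200).
#' @param mito_multiplier multiple of the ambient mitochondrial percentage
#'   at which a barcode is discarded (default 2).
#' @param cap ambient read cap (default 100).
#' @param src optional precomputed [species_read_counts()] table.
#' @return A `SpeciesCall` data.frame: `barcode`, `label`
#'   (`pending`/`empty_like`/`low_quality`), read-`majority` species,
#'   `reasons` (rule ids, `;`-separated).
#' @export
prefilter <- function(x, ambient, min_genes = 200, mito_multiplier = 2,
                      cap = 100, src = NULL) {
  if (is.null(src)) src <- species_read_counts(x)
  total <- src$human_reads + src$mouse_reads
  calls <- new_species_call(src$barcode,
                            ifelse(src$human_reads >= src$mouse_reads, "human", "mouse"))
  calls <- set_label(calls, total < cap, "empty_like", "sub_ambient_cap")
  pending <- calls$label == "pending"
  fail_genes <- src$human_genes < min_genes & src$mouse_genes < min_genes
  calls <- set_label(calls, pending & fail_genes, "low_quality", "min_genes")
  pending <- calls$label == "pending"
  mito_fail <- function(reads, pct, amb) {
    amb > 0 & reads >= 1 & pct >= mito_multiplier * amb
  }
  fail_mito <- mito_fail(src$human_reads, src$human_mito_pct, ambient$mito_pct[["human"]]) |
    mito_fail(src$mouse_reads, src$mouse_mito_pct, ambient$mito_pct[["mouse"]])
  calls <- set_label(calls, pending & fail_mito, "low_quality", "mito_vs_ambient")
  calls
}

#' @export
print.SpeciesCall <- function(x, ...) {
  cat("SpeciesCall for", nrow(x), "barcodes:\n")
  print(table(x$label))
  invisible(x)
}

#' Correlate barcodes with reference atlas profiles, per species
#'
#' For each species, counts are restricted to that species' genes shared
#' with the atlas, depth-normalized within the restriction (counts per
#' 10,000, log1p) and Pearson-correlated with each atlas profile of that
#' species, normalized the same way. The best correlation per species is
#' min-max rescaled to \[0, 1\] across the given barcodes. Restricting each
#' axis to its own species' genes means a droplet containing one cell of
#' each species scores like a genuine cell on both axes.
#'
#' @param x a combined-view [CountMatrix()].
#' @param atlas a `ReferenceAtlas` (see [make_atlas()]) or compatible list
#'   with `profiles` (genes x profiles), `species`, `feature_id`.
#' @param barcodes barcodes to score (default all).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `data.frame` of class `CorrelationResult`: per barcode
#'   `best_corr_human`, `best_corr_mouse` (raw, 0 for constant vectors),
#'   `norm_corr_human`, `norm_corr_mouse`.
#' @export
atlas_correlation <- function(x, atlas, barcodes = x$barcodes,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_count_matrix(x)
  if (length(unique(atlas$species)) < 2)
    stop_integrity("atlas must contain profiles of both species")
  xs <- subset_barcodes(x, barcodes)
  best <- list()
  for (s in c("human", "mouse")) {
    rows <- which(xs$features$species == s &
                    xs$features$feature_id %in% atlas$feature_id)
    if (length(rows) < 50)
      stop_integrity("fewer than 50 shared ", s, " genes with the atlas")
    prof <- atlas$profiles[match(xs$features$feature_id[rows], atlas$feature_id),
                           atlas$species == s, drop = FALSE]
    prof <- sweep(prof, 2, pmax(colSums(prof), 1e-12), "/")
    prof <- log1p(prof * 1e4)
    cn <- lognorm(xs$counts[rows, , drop = FALSE])
    if (method == "spearman") {
      prof <- apply(prof, 2, rank)
    }
    n <- ncol(cn)
    bb <- numeric(n)
    chunk <- 2000L
    for (start in seq(1L, n, by = chunk)) {
      cols <- start:min(start + chunk - 1L, n)
      dm <- as.matrix(cn[, cols, drop = FALSE])
      if (method == "spearman") dm <- apply(dm, 2, rank)
      cc <- suppressWarnings(cor(dm, prof))
      cc[is.na(cc)] <- 0
      bb[cols] <- apply(cc, 1, max)
    }
    best[[s]] <- bb
  }
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  structure(data.frame(barcode = xs$barcodes,
                       best_corr_human = best$human,
                       best_corr_mouse = best$mouse,
                       norm_corr_human = minmax(best$human),
                       norm_corr_mouse = minmax(best$mouse),
                       stringsAsFactors = FALSE),
            class = c("CorrelationResult", "data.frame"))
}

# distribution-free lower bound of the 99% CI of the median: the order
# statistic at rank floor((n - z * sqrt(n)) / 2)
median_ci_lower <- function(x, ci_level = 0.99) {
  n <- length(x)
  z <- qnorm(1 - (1 - ci_level) / 2)
  r <- max(1L, floor((n - z * sqrt(n)) / 2))
  sort(x)[r]
}

#' Correlation cutoffs separating cells from cross-species doublets
#'
#' For each species, the cutoff is derived from the normalized own-species
#' correlations of barcodes whose read majority is that species. The
#' default places it `mad_multiplier` scaled MADs below the group median: a
#' bar low enough that genuine cells (and the same-species half of a
#' doublet) clear it, yet far above the correlation the other species'
#' cells show on this axis. `method = "median_ci"` instead uses the lower
#' bound of the distribution-free `ci_level` confidence interval of the
#' group median (order statistic at rank `floor((n - z*sqrt(n))/2)`), which
#' sits just below the group median itself. Groups smaller than
#' `min_group` always fall back to the MAD rule.
#'
#' @param corr a [atlas_correlation()] result.
#' @param majority per-barcode read-majority species, aligned with `corr`.
#' @param method `"mad"` (default) or `"median_ci"`.
#' @param ci_level confidence level for `"median_ci"`.
#' @param mad_multiplier MADs below the median for `"mad"` (default 3).
#' @param min_group groups below this size use the MAD fallback.
#' @return List of class `SpeciesCutoffs`: `cutoff_human`, `cutoff_mouse`
#'   (normalized correlation scale), `method`.
#' @export
compute_cutoffs <- function(corr, majority, method = c("mad", "median_ci"),
                            ci_level = 0.99, mad_multiplier = 3,
                            min_group = 20L) {
  method <- match.arg(method)
  stopifnot(nrow(corr) == length(majority))
  one <- function(s) {
    v <- corr[[paste0("norm_corr_", s)]][majority == s]
    if (length(v) == 0) stop_integrity("no barcodes with read majority ", s)
    if (method == "median_ci" && length(v) >= min_group) {
      median_ci_lower(v, ci_level)
    } else {
      if (method == "median_ci")
        warning("majority group ", s, " has fewer than ", min_group,
                " barcodes; falling back to median - ", mad_multiplier, " MADs")
      max(median(v) - mad_multiplier * mad_floor(v), 0)
    }
  }
  structure(list(cutoff_human = one("human"), cutoff_mouse = one("mouse"),
                 method = method),
            class = "SpeciesCutoffs")
}

#' @export
print.SpeciesCutoffs <- function(x, ...) {
  cat(sprintf("SpeciesCutoffs (%s): human %.3f, mouse %.3f\n",
              x$method, x$cutoff_human, x$cutoff_mouse))
  invisible(x)
}

#' Classify pending barcodes as human, mouse or cross-species doublet
#'
#' Rules, in order: (1) normalized correlation at or above the cutoff for
#' both species: `cross_doublet`. (2) Otherwise the barcode belongs to its
#' read-majority species; if its best raw correlation points to the other
#' species it is internally inconsistent and labelled `discrepant`.
#' (3) Otherwise it is a singlet of the majority species.
#'
#' @param calls a `SpeciesCall` (from [prefilter()]).
#' @param corr a [atlas_correlation()] result covering the pending barcodes.
#' @param cutoffs a [compute_cutoffs()] result.
#' @return The updated `SpeciesCall`.
#' @export
classify_barcodes <- function(calls, corr, cutoffs) {
  idx <- match(calls$barcode, corr$barcode)
  pending <- which(calls$label == "pending" & !is.na(idx))
  ci <- idx[pending]
  both <- corr$norm_corr_human[ci] >= cutoffs$cutoff_human &
    corr$norm_corr_mouse[ci] >= cutoffs$cutoff_mouse
  calls <- set_label(calls, pending[both], "cross_doublet", "high_corr_both")
  rest <- pending[!both]; ri <- idx[rest]
  corr_best <- ifelse(corr$best_corr_human[ri] >= corr$best_corr_mouse[ri],
                      "human", "mouse")
  mismatch <- corr_best != calls$majority[rest]
  calls <- set_label(calls, rest[mismatch], "discrepant", "majority_corr_mismatch")
  ok <- rest[!mismatch]
  calls$label[ok] <- calls$majority[ok]
  calls
}

#' Remove minority-species barcodes from species-pure clusters
#'
#' Clusters the called cells (log-normalized expression, PCA, kNN graph,
#' Louvain communities). When every cluster is at least
#' `1 - minority_fraction` one species, the clustering cleanly separates
#' species and minority-species barcodes within each cluster are relabelled
#' `discrepant`; otherwise calls are returned unchanged.
#'
#' @param x combined-view [CountMatrix()].
#' @param calls a `SpeciesCall` with singlet labels assigned.
#' @param minority_fraction cluster purity tolerance (default 0.10).
#' @param n_pcs,knn_k embedding and graph parameters.
#' @param seed RNG seed for the embedding and community detection.
#' @return List: updated `calls`, cluster `membership` (named by barcode),
#'   `separated` flag.
#' @export
cluster_minority_removal <- function(x, calls, minority_fraction = 0.10,
                                     n_pcs = 20L, knn_k = 20L, seed = 1L) {
  sel <- which(calls$label %in% c("human", "mouse"))
  if (length(sel) < 10)
    return(list(calls = calls, membership = NULL, separated = FALSE))
  xs <- subset_barcodes(x, calls$barcode[sel])
  ln <- lognorm(xs$counts)
  hv <- top_variable_genes(ln, 2000L)
  emb <- pca_embed(ln[hv, , drop = FALSE], n_pcs = n_pcs, seed = seed)
  memb <- knn_cluster(emb, k = knn_k, seed = seed)
  labs <- calls$label[sel]
  separated <- TRUE
  minority_idx <- integer(0)
  for (cl in unique(memb)) {
    in_cl <- which(memb == cl)
    frac_h <- mean(labs[in_cl] == "human")
    if (max(frac_h, 1 - frac_h) < 1 - minority_fraction) {
      separated <- FALSE
      break
    }
    maj <- if (frac_h >= 0.5) "human" else "mouse"
    minority_idx <- c(minority_idx, in_cl[labs[in_cl] != maj])
  }
  if (separated && length(minority_idx))
    calls <- set_label(calls, sel[minority_idx], "discrepant", "cluster_minority")
  list(calls = calls,
       membership = setNames(memb, calls$barcode[sel]),
       separated = separated)
}

#' Smoothed-expression copy-number (aneuploidy) score
#'
#' A light-weight stand-in for full copy-number inference: per cell,
#' log-normalized expression of one species' genes is ordered along the
#' genome, smoothed with a centred moving average of `window` genes,
#' centred on the median smoothed profile over all cells, and scored by the
#' variance of the result. Aneuploid cells carry contiguous gained or lost
#' blocks, which survive smoothing and inflate the variance; diploid cells
#' flatten out. Ploidy is called by a two-component 1-D split (k-means) of
#' the scores, with the threshold midway between component means; when the
#' components are not separated (`sep_ratio`) everyone is called diploid.
#'
#' @param x a [CountMatrix()] restricted to one species (a matching view or
#'   a [split_by_species()] output).
#' @param barcodes barcodes to score (default all).
#' @param window moving-average window in genes (default 101).
#' @param min_genes cells expressing fewer genes than this are
#'   `not_assessable` (default 100).
#' @param sep_ratio minimum ratio of k-means component means for an
#'   aneuploid component to be accepted (default 2).
#' @param seed RNG seed for the component split.
#' @return `data.frame` of class `CnvResult`: `barcode`, `score`,
#'   `ploidy` (`aneuploid` / `diploid` / `not_assessable`).
#' @export
cnv_score <- function(x, barcodes = x$barcodes, window = 101L,
                      min_genes = 100L, sep_ratio = 2, seed = 1L) {
  validate_count_matrix(x)
  if (length(unique(x$features$species)) != 1)
    stop_integrity("cnv_score needs a single-species gene space")
  if (nrow(x$counts) < 200)
    stop_integrity("need >= 200 genes with genomic order for copy-number smoothing")
  xs <- subset_barcodes(x, barcodes)
  ord <- order(xs$features$genomic_index)
  ln <- as.matrix(lognorm(xs$counts)[ord, , drop = FALSE])
  G <- nrow(ln)
  half <- (min(window, G) - 1L) %/% 2L
  cs <- apply(ln, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(G) - half - 1L, 0L)
  hi <- pmin(seq_len(G) + half, G)
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
  ctr <- sm - apply(sm, 1, median)
  score <- colMeans(ctr^2) - colMeans(ctr)^2
  genes_expr <- Matrix::colSums(xs$counts > 0)
  assess <- genes_expr >= min_genes
  ploidy <- rep("not_assessable", length(score))
  if (sum(assess) >= 4 && var(score[assess]) > 0) {
    set.seed(seed)
    km <- kmeans(score[assess], centers = 2, nstart = 5)
    cmean <- sort(as.vector(km$centers))
    if (cmean[1] <= 0 || cmean[2] / max(cmean[1], 1e-12) >= sep_ratio) {
      thr <- mean(cmean)
      ploidy[assess] <- ifelse(score[assess] > thr, "aneuploid", "diploid")
    } else {
      ploidy[assess] <- "diploid"
    }
  } else {
    ploidy[assess] <- "diploid"
  }
  structure(data.frame(barcode = xs$barcodes, score = score, ploidy = ploidy,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("CnvResult", "data.frame"))
}

#' Apply copy-number tumour rules to species calls
#'
#' Aneuploid barcodes are tumour cells: with human read majority they are
#' retained as human even when their atlas correlation was inconsistent
#' (tumour expression need not resemble any normal profile). Barcodes with
#' a valid (assessable) copy-number result on the human gene space but a
#' mouse read majority contain both species' material and become
#' cross-species doublets. Unassessable barcodes are untouched.
#'
#' @param calls a `SpeciesCall`.
#' @param cnv a [cnv_score()] result on the human gene space.
#' @return Updated `SpeciesCall`.
#' @export
apply_tumor_rules <- function(calls, cnv) {
  idx <- match(calls$barcode, cnv$barcode)
  known <- !is.na(idx)
  ploidy <- rep("not_assessable", nrow(calls))
  ploidy[known] <- cnv$ploidy[idx[known]]
  eligible <- !calls$label %in% c("empty_like", "low_quality")
  rescue <- eligible & ploidy == "aneuploid" & calls$majority == "human" &
    calls$label != "human"
  calls <- set_label(calls, rescue, "human", "tumor_rescue")
  to_doublet <- eligible & ploidy %in% c("aneuploid", "diploid") &
    calls$majority == "mouse" & calls$label != "cross_doublet"
  calls <- set_label(calls, to_doublet, "cross_doublet", "cnv_mouse_majority")
  calls
}

#' Run prefilter, correlation and classification in one call
#'
#' Convenience wrapper for pipeline steps 1-2: ambient profile, prefilter,
#' atlas correlation of surviving barcodes, cutoffs, classification,
#' cluster minority removal and (optionally) copy-number tumour rules.
#'
#' @param x combined-view [CountMatrix()].
#' @param atlas a `ReferenceAtlas`.
#' @param config a [pipeline_config()].
#' @param use_cnv apply [cnv_score()]/[apply_tumor_rules()] (for libraries
#'   containing tumour cells).
#' @return List: `calls`, `ambient`, `corr`, `cutoffs`, `src`,
#'   `clusters`, `cnv` (or `NULL`).
#' @export
call_species <- function(x, atlas, config = pipeline_config(), use_cnv = FALSE) {
  src <- species_read_counts(x)
  ambient <- estimate_ambient_profile(x, cap = config$ambient_read_cap)
  calls <- prefilter(x, ambient, min_genes = config$min_genes,
                     mito_multiplier = config$mito_ambient_multiplier,
                     cap = config$ambient_read_cap, src = src)
  kept <- calls$barcode[calls$label == "pending"]
  corr <- atlas_correlation(x, atlas, barcodes = kept,
                            method = config$corr_method)
  cutoffs <- compute_cutoffs(corr, calls$majority[match(kept, calls$barcode)],
                             method = config$cutoff_method,
                             ci_level = config$ci_level,
                             mad_multiplier = config$qc_mad_multiplier)
  calls <- classify_barcodes(calls, corr, cutoffs)
  cl <- cluster_minority_removal(x, calls,
                                 minority_fraction = config$cluster_minority_fraction,
                                 n_pcs = config$n_pcs, knn_k = config$knn_k,
                                 seed = config$seed)
  calls <- cl$calls
  cnv <- NULL
  if (use_cnv) {
    human <- split_by_species(x)$human
    keep_bc <- calls$barcode[!calls$label %in% c("empty_like", "low_quality")]
    cnv <- cnv_score(human, barcodes = keep_bc, seed = config$seed)
    calls <- apply_tumor_rules(calls, cnv)
  }
  list(calls = calls, ambient = ambient, corr = corr, cutoffs = cutoffs,
       src = src, clusters = cl$membership, cnv = cnv)
}
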