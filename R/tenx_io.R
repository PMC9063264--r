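# 10x Genomics Market Exchange directory I/O.
#
# A count directory holds matrix.mtx, features.tsv (or genes.tsv) and
# barcodes.tsv, each optionally gzipped. Species is taken from the features
# genome column when present, else from the Cell Ranger combined-reference
# feature-id prefix ("GRCh38_" / "mm10_"), else from an explicit map.

gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

open_text <- function(path) if (gzipped(path)) gzfile(path, "rt") else file(path, "rt")

find_tenx_file <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    p <- file.path(dir, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  stop_format("no ", stems[1], "[.gz] in ", dir)
}

genome_to_species <- function(genome) {
  sp <- rep(NA_character_, length(genome))
  sp[grepl("GRCh|hg19|hg38|human", genome, ignore.case = TRUE)] <- "human"
  sp[grepl("mm10|mm39|GRCm|mouse", genome, ignore.case = TRUE)] <- "mouse"
  sp
}

#' Read a 10x Market Exchange count directory
#'
#' Reads `matrix.mtx[.gz]`, `features.tsv[.gz]` (or `genes.tsv`) and
#' `barcodes.tsv[.gz]`. Gzip is detected from the file's magic bytes, not
#' its extension. Species per feature is inferred from the features genome
#' column when present, else from a `GRCh38_`/`mm10_` feature-id prefix,
#' else taken from `species_map`. Mitochondrial genes are recognised by the
#' `MT-`/`mt-` gene-name prefix. Extra columns 5-7 of the features file, if
#' present, are read back as chromosome, genomic index and homolog id (the
#' extension written by [write_tenx()]).
#'
#' @param dir path to the count directory.
#' @param view reference view the matrix was aligned to; `"auto"` picks
#'   `"combined"` when both species occur, else the single species present.
#' @param species_map optional named character vector `feature_id -> species`
#'   used when neither a genome column nor an id prefix identifies species.
#' @param mito_genes optional character vector of mitochondrial gene names
#'   overriding the prefix rule.
#' @return A [CountMatrix()].
#' @export
read_tenx <- function(dir, view = "auto", species_map = NULL, mito_genes = NULL) {
  if (!dir.exists(dir)) stop_format("no such directory: ", dir)
  mtx_path <- find_tenx_file(dir, "matrix.mtx")
  feat_path <- find_tenx_file(dir, c("features.tsv", "genes.tsv"))
  bc_path <- find_tenx_file(dir, "barcodes.tsv")

  con <- open_text(mtx_path)
  m <- tryCatch(Matrix::readMM(con), error = function(e)
    stop_format("malformed MTX file ", mtx_path, ": ", conditionMessage(e)))
  close(con)

  fcon <- open_text(feat_path)
  feats <- read.delim(fcon, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
  tryCatch(close(fcon), error = function(e) NULL)
  bcon <- open_text(bc_path)
  barcodes <- readLines(bcon)
  close(bcon)

  if (nrow(feats) != nrow(m))
    stop_integrity("MTX declares ", nrow(m), " features but ", basename(feat_path),
                   " has ", nrow(feats), " lines")
  if (length(barcodes) != ncol(m))
    stop_integrity("MTX declares ", ncol(m), " barcodes but ", basename(bc_path),
                   " has ", length(barcodes), " lines")

  fid <- feats[[1]]
  fname <- if (ncol(feats) >= 2) feats[[2]] else fid
  species <- rep(NA_character_, nrow(feats))
  if (ncol(feats) >= 4) species <- genome_to_species(feats[[4]])
  pre <- is.na(species)
  species[pre & startsWith(fid, "GRCh38_")] <- "human"
  species[pre & startsWith(fid, "mm10_")] <- "mouse"
  if (anyNA(species) && !is.null(species_map))
    species[is.na(species)] <- unname(species_map[fid[is.na(species)]])
  if (anyNA(species))
    stop_format("species undeterminable for ", sum(is.na(species)),
                " features (no genome column, id prefix, or species_map entry)")

  ft <- feature_table(
    feature_id = fid, feature_name = fname, species = species,
    chromosome = if (ncol(feats) >= 5) feats[[5]] else NA_character_,
    genomic_index = if (ncol(feats) >= 6) as.integer(feats[[6]]) else NULL,
    homolog_id = if (ncol(feats) >= 7) ifelse(feats[[7]] == "", NA, feats[[7]]) else NA_character_,
    mito_genes = mito_genes
  )
  if (identical(view, "auto"))
    view <- if (length(unique(species)) == 2L) "combined" else unique(species)
  CountMatrix(m, ft, barcodes, view = view)
}

#' Write a 10x Market Exchange count directory
#'
#' Writes `matrix.mtx` in 1-based coordinate format with header
#' `%%MatrixMarket matrix coordinate integer general`, a `features.tsv`
#' with columns id / name / type / genome plus chromosome, genomic index
#' and homolog id (so annotation survives a round trip), and
#' `barcodes.tsv`.
#'
#' @param x a [CountMatrix()].
#' @param dir output directory (created if absent).
#' @param gzip write gzipped files.
#' @return `dir`, invisibly.
#' @export
write_tenx <- function(x, dir, gzip = FALSE) {
  validate_count_matrix(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  opener <- if (gzip) gzfile else file

  m <- as(x$counts, "TsparseMatrix")
  mcon <- opener(file.path(dir, paste0("matrix.mtx", ext)), "wt")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), mcon)
  if (length(m@x))
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), mcon)
  close(mcon)

  genome <- ifelse(x$features$species == "human", "GRCh38", "mm10")
  fcon <- opener(file.path(dir, paste0("features.tsv", ext)), "wt")
  writeLines(paste(x$features$feature_id, x$features$feature_name,
                   "Gene Expression", genome,
                   ifelse(is.na(x$features$chromosome), "", x$features$chromosome),
                   x$features$genomic_index,
                   ifelse(is.na(x$features$homolog_id), "", x$features$homolog_id),
                   sep = "\t"), fcon)
  close(fcon)

  bcon <- opener(file.path(dir, paste0("barcodes.tsv", ext)), "wt")
  writeLines(x$barcodes, bcon)
  close(bcon)
  invisible(dir)
}

#' Split a combined-view matrix into per-species matrices
#'
#' Both outputs keep every barcode; the feature columns partition the
#' input's, so all counts are conserved.
#'
#' @param x a combined-view [CountMatrix()].
#' @return A list with elements `human` and `mouse`.
#' @export
split_by_species <- function(x) {
  validate_count_matrix(x)
  if (x$view != "combined")
    stop_integrity("split_by_species requires a combined view, got ", x$view)
  out <- lapply(c(human = "human", mouse = "mouse"), function(s) {
    idx <- which(x$features$species == s)
    ft <- x$features[idx, , drop = FALSE]
    rownames(ft) <- NULL
    CountMatrix(x$counts[idx, , drop = FALSE], ft, x$barcodes, view = s)
  })
  out
}

#' Per-barcode read tallies by species
#'
#' For each barcode of a combined-view matrix, counts reads and expressed
#' genes (count >= 1) separately for human and mouse features, and the
#' mitochondrial read percentage within each species' reads (0 when that
#' species has no reads).
#'
#' @param x a combined-view [CountMatrix()].
#' @return A `data.frame` with one row per barcode: `barcode`,
#'   `human_reads`, `mouse_reads`, `human_genes`, `mouse_genes`,
#'   `human_mito_pct`, `mouse_mito_pct` (percentages on a 0-100 scale).
#' @export
species_read_counts <- function(x) {
  validate_count_matrix(x)
  if (x$view != "combined")
    stop_integrity("species_read_counts requires a combined view")
  tally <- function(s) {
    idx <- x$features$species == s
    sub <- x$counts[idx, , drop = FALSE]
    mito <- x$counts[idx & x$features$is_mito, , drop = FALSE]
    tot <- Matrix::colSums(sub)
    list(reads = tot,
         genes = Matrix::colSums(sub > 0),
         mito_pct = ifelse(tot > 0, 100 * Matrix::colSums(mito) / tot, 0))
  }
  h <- tally("human"); m <- tally("mouse")
  data.frame(barcode = x$barcodes,
             human_reads = h$reads, mouse_reads = m$reads,
             human_genes = h$genes, mouse_genes = m$genes,
             human_mito_pct = h$mito_pct, mouse_mito_pct = m$mito_pct,
             row.names = NULL, stringsAsFactors = FALSE)
}
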