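# Reference-atlas table I/O: one row per profile, a species column, then
# one column per gene (mean expression). Any atlas of cell-type mean
# profiles can be supplied this way in place of the simulator's.

#' Write a reference atlas as a tab-separated table
#'
#' @param atlas a `ReferenceAtlas`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_atlas_tsv <- function(atlas, path) {
  m <- t(atlas$profiles)
  df <- data.frame(profile = rownames(m), species = atlas$species,
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference atlas from a tab-separated table
#'
#' Expects columns `profile`, `species`, then one column per gene.
#'
#' @param path input file.
#' @return A `ReferenceAtlas`.
#' @export
read_atlas_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("profile", "species") %in% names(df)))
    stop_format("atlas table needs 'profile' and 'species' columns")
  genes <- setdiff(names(df), c("profile", "species"))
  prof <- t(as.matrix(df[, genes, drop = FALSE]))
  colnames(prof) <- df$profile
  structure(list(profiles = prof, species = df$species, feature_id = genes),
            class = "ReferenceAtlas")
}
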