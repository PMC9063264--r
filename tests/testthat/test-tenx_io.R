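test_that("write/read round trip is entry-exact, plain and gzipped", {
  sim <- small_sim()
  for (gz in c(FALSE, TRUE)) {
    d <- withr::local_tempdir()
    write_tenx(sim$combined, d, gzip = gz)
    back <- read_tenx(d)
    expect_identical(unname(as.matrix(back$counts)),
                     unname(as.matrix(sim$combined$counts)))
    expect_identical(back$barcodes, sim$combined$barcodes)
    expect_identical(back$features$species, sim$combined$features$species)
    expect_identical(back$features$is_mito, sim$combined$features$is_mito)
    expect_identical(back$features$genomic_index, sim$combined$features$genomic_index)
    expect_identical(back$features$homolog_id, sim$combined$features$homolog_id)
    expect_identical(back$view, "combined")
  }
})

test_that("MTX files use the 1-based integer coordinate convention", {
  m <- toy_combined()
  d <- withr::local_tempdir()
  write_tenx(m, d)
  lines <- readLines(file.path(d, "matrix.mtx"))
  expect_identical(lines[1], "%%MatrixMarket matrix coordinate integer general")
  expect_identical(lines[2], "4 4 6")
  # in-memory entry [1,1] = 15 appears as "1 1 15"
  expect_true("1 1 15" %in% lines[-(1:2)])
})

test_that("an empty matrix writes valid files with zero data lines", {
  ft <- feature_table("hA", "HGENE1", "human")
  m <- CountMatrix(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(1, 0)),
                   ft, character(0), view = "human")
  d <- withr::local_tempdir()
  write_tenx(m, d)
  back <- read_tenx(d, view = "human")
  expect_identical(dim(back$counts), c(1L, 0L))
})

test_that("species comes from the genome column when present", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 1", "1 1 3"), file.path(d, "matrix.mtx"))
  writeLines(c("g1\tG1\tGene Expression\tGRCh38",
               "g2\tG2\tGene Expression\tGRCh38"), file.path(d, "features.tsv"))
  writeLines("bc1", file.path(d, "barcodes.tsv"))
  m <- read_tenx(d)
  expect_true(all(m$features$species == "human"))
  expect_identical(m$view, "human")
})

test_that("Cell Ranger id prefixes determine species when no genome column", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 2", "1 1 3", "2 1 4"), file.path(d, "matrix.mtx"))
  writeLines(c("GRCh38_ENSG1\tGRCh38_TP53", "mm10_ENSMUSG1\tmm10_Trp53"),
             file.path(d, "features.tsv"))
  writeLines("bc1", file.path(d, "barcodes.tsv"))
  m <- read_tenx(d)
  expect_identical(m$features$species, c("human", "mouse"))
})

test_that("header/feature-count mismatch raises an integrity error", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "10 1 1", "1 1 2"), file.path(d, "matrix.mtx"))
  writeLines(sprintf("g%d\tG%d\tGene Expression\tGRCh38", 1:9, 1:9),
             file.path(d, "features.tsv"))
  writeLines("bc1", file.path(d, "barcodes.tsv"))
  expect_error(read_tenx(d), class = "xdeconv_integrity_error")
})

test_that("missing files raise a format error", {
  d <- withr::local_tempdir()
  expect_error(read_tenx(d), class = "xdeconv_format_error")
  dir.create(file.path(d, "x"))
  expect_error(read_tenx(file.path(d, "x")), class = "xdeconv_format_error")
})

test_that("split_by_species conserves every count and keeps all barcodes", {
  sim <- small_sim()
  sp <- split_by_species(sim$combined)
  expect_identical(sp$human$barcodes, sim$combined$barcodes)
  expect_identical(sp$mouse$barcodes, sim$combined$barcodes)
  expect_equal(nrow(sp$human$counts) + nrow(sp$mouse$counts),
               nrow(sim$combined$counts))
  expect_equal(Matrix::colSums(sp$human$counts) + Matrix::colSums(sp$mouse$counts),
               Matrix::colSums(sim$combined$counts))
  expect_error(split_by_species(sp$human), class = "xdeconv_integrity_error")
})

test_that("a two-barcode toy splits exactly", {
  ft <- feature_table(c("hA", "mA"), c("HG", "mg"), c("human", "mouse"))
  m <- CountMatrix(matrix(c(3, 1, 0, 7), nrow = 2), ft, c("b1", "b2"), "combined")
  sp <- split_by_species(m)
  expect_equal(as.vector(sp$human$counts), c(3, 0))
  expect_equal(as.vector(sp$mouse$counts), c(1, 7))
})

test_that("species_read_counts tallies reads, genes and mito percent", {
  src <- species_read_counts(toy_combined())
  # bc1: 20 human reads on 2 genes, 5 of them on the MT- gene
  expect_equal(src$human_reads[1], 20)
  expect_equal(src$human_genes[1], 2)
  expect_equal(src$human_mito_pct[1], 25)
  expect_equal(src$mouse_reads[1], 0)
  expect_equal(src$mouse_mito_pct[1], 0)
  # all-zero barcode: everything 0
  expect_true(all(unlist(src[4, -1]) == 0))
})

test_that("species_read_counts matches a brute-force loop on random data", {
  sim <- small_sim()
  keep <- sample(sim$combined$barcodes, 50)
  sub <- xdeconv:::subset_barcodes(sim$combined, keep)
  src <- species_read_counts(sub)
  dense <- as.matrix(sub$counts)
  ft <- sub$features
  for (j in seq_along(keep)) {
    for (s in c("human", "mouse")) {
      rows <- ft$species == s
      tot <- sum(dense[rows, j])
      expect_equal(unname(src[[paste0(s, "_reads")]][j]), tot)
      expect_equal(unname(src[[paste0(s, "_genes")]][j]),
                       sum(dense[rows, j] >= 1))
      expect_equal(unname(src[[paste0(s, "_mito_pct")]][j]),
                   if (tot > 0) 100 * sum(dense[rows & ft$is_mito, j]) / tot else 0)
    }
  }
})
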