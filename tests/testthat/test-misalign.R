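make_view_pair <- function(matching_counts, combined_counts_own,
                           combined_counts_other = NULL) {
  # one human gene audit universe with an optional mouse gene in combined
  ftm <- feature_table("hA", "HG1", "human")
  n <- length(matching_counts)
  bcs <- paste0("b", seq_len(n))
  matching <- CountMatrix(matrix(matching_counts, nrow = 1), ftm, bcs, "human")
  ftc <- feature_table(c("hA", "mA"), c("HG1", "mg1"), c("human", "mouse"))
  if (is.null(combined_counts_other)) combined_counts_other <- rep(0, n)
  combined <- CountMatrix(rbind(combined_counts_own, combined_counts_other),
                          ftc, bcs, "combined")
  list(matching = matching, combined = combined)
}

test_that("identical views show zero loss and zero misalignment", {
  vp <- make_view_pair(c(10, 20), c(10, 20))
  rep <- compare_views(vp$matching, vp$combined)
  expect_equal(rep$per_gene$read_loss_pct, 0)
  expect_equal(rep$reads_misaligned_to_other, 0)
})

test_that("read loss is the fractional count difference vs the matching view", {
  vp <- make_view_pair(100, 35)
  rep <- compare_views(vp$matching, vp$combined)
  expect_equal(rep$per_gene$read_loss_pct, 65)
})

test_that("a barcode absent from a view is an error", {
  vp <- make_view_pair(c(5, 5), c(5, 5))
  expect_error(compare_views(vp$matching, vp$combined, barcodes = "nope"),
               class = "xdeconv_integrity_error")
})

test_that("audit aggregates equal the ledger exactly on simulated data", {
  sim <- small_sim()
  for (sp in c("human", "mouse")) {
    view <- if (sp == "human") sim$human_view else sim$mouse_view
    bcs <- sim$truth$barcode[sim$truth$class == paste0(sp, "_singlet")]
    rep <- compare_views(view, sim$combined, barcodes = bcs)
    la <- xdeconv:::ledger_aggregates(sim$ledger, bcs, sp)
    expect_equal(rep$reads_misaligned_to_other, la$misaligned_to_other)
    expect_equal(rep$matching_total, la$matching_view_total)
    expect_equal(multimap_increment(la$multimap_matching, la$multimap_combined),
                 sum(sim$ledger$n_multi[sim$ledger$barcode %in% bcs]))
  }
})

test_that("per-gene audit counts equal ledger-derived counts exactly", {
  sim <- small_sim()
  bcs <- sim$combined$barcodes
  rep <- compare_views(sim$human_view, sim$combined, barcodes = bcs)
  l <- sim$ledger
  prm <- sim$params
  gid <- match(l$feature_id, prm$features$feature_id)
  G <- nrow(sim$human_view$counts)
  # matching count of human gene g: all its origin reads + mouse-partner crossing
  own_tot <- tapply(l$n_matching[l$origin_species == "human"],
                    gid[l$origin_species == "human"], sum)
  cross_in <- tapply(l$n_cross[l$origin_species == "mouse"],
                     prm$partner[gid[l$origin_species == "mouse"]], sum)
  expect_m <- numeric(G)
  expect_m[as.integer(names(own_tot))] <- own_tot
  idx <- as.integer(names(cross_in))
  expect_m[idx] <- expect_m[idx] + cross_in
  expect_equal(unname(rep$per_gene$matching_count), expect_m)
  # combined count of human gene g: its correct reads + mouse-partner crossing
  own_cor <- tapply(l$n_correct[l$origin_species == "human"],
                    gid[l$origin_species == "human"], sum)
  expect_c <- numeric(G)
  expect_c[as.integer(names(own_cor))] <- own_cor
  expect_c[idx] <- expect_c[idx] + cross_in
  expect_equal(unname(rep$per_gene$combined_count), expect_c)
})

test_that("error_rate follows its two-addend definition", {
  expect_equal(error_rate(5, 50, 58, 1000), 13 / 1000)
  expect_equal(error_rate(0, 7, 7, 100), 0)
  expect_equal(error_rate(0, 10, 4, 100), 0)  # increment floored at zero
  expect_error(error_rate(1, 0, 0, 0), class = "xdeconv_integrity_error")
})

test_that("multimap increment matches the published placenta library tally", {
  expect_equal(multimap_increment(1499012, 1665421), 166409)
  expect_equal(multimap_increment(5, 5), 0)
  expect_equal(multimap_increment(10, 2), 0)
})

test_that("misaligned-gene calls need both expression and divergence", {
  vp <- make_view_pair(matching_counts = rep(0, 1), combined_counts_own = 0)
  # build a report by hand covering the three cases over 100 cells
  rep <- structure(list(
    per_gene = data.frame(
      feature_id = c("g_low", "g_hit", "g_small"),
      matching_count = c(5, 50, 50),
      combined_count = c(2.5, 44, 46),
      read_loss_pct = c(50, 12, 8),
      avg_count_per_cell = c(0.05, 0.5, 0.5)),
    n_cells = 100), class = "MisalignmentReport")
  expect_identical(call_misaligned_genes(rep), "g_hit")
  # gain is flagged under the default absolute criterion, not under loss-only
  rep$per_gene$combined_count[3] <- 60
  expect_setequal(call_misaligned_genes(rep), c("g_hit", "g_small"))
  expect_identical(call_misaligned_genes(rep, direction = "loss"), "g_hit")
})
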