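test_that("the read-fate ledger balances exactly for every (barcode, gene)", {
  l <- small_sim()$ledger
  expect_true(all(l$n_matching == l$n_correct + l$n_cross + l$n_multi))
  expect_true(all(l$n_correct >= 0 & l$n_cross >= 0 & l$n_multi >= 0))
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- small_config()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$combined$counts), as.matrix(b$combined$counts))
  expect_identical(as.matrix(a$human_view$counts), as.matrix(b$human_view$counts))
  expect_identical(a$truth, b$truth)
  expect_identical(a$ledger, b$ledger)
})

test_that("truth classes partition the barcodes at the configured counts", {
  sim <- small_sim()
  cfg <- small_config()
  expect_identical(sort(unique(sim$truth$barcode)), sort(sim$combined$barcodes))
  tab <- table(sim$truth$class)
  for (cl in names(cfg$n_droplets))
    expect_equal(unname(tab[cl]), unname(cfg$n_droplets[cl]),
                 ignore_attr = TRUE)
})

test_that("with no misalignment and no ambient, views agree entry-exactly", {
  cfg <- sim_config(seed = 21, n_genes = 300, n_homolog_pairs = 80,
                    n_droplets = c(human_singlet = 60, mouse_singlet = 60),
                    rho_fixed = 0, m_cross_mean = 0, m_multi_mean = 0,
                    m_hot_frac = 0, n_trap_genes = 0, qc_outlier_fraction = 0)
  sim <- simulate_dataset(cfg)
  sp <- split_by_species(sim$combined)
  expect_identical(as.matrix(sp$human$counts), as.matrix(sim$human_view$counts))
  expect_identical(as.matrix(sp$mouse$counts), as.matrix(sim$mouse_view$counts))
})

test_that("total simulated reads match the ledger and the matching views", {
  sim <- small_sim()
  total <- sum(sim$ledger$n_matching)
  comp <- sim$composition
  expect_equal(total, sum(comp$cell_reads_human + comp$cell_reads_mouse +
                            comp$ambient_reads_human + comp$ambient_reads_mouse))
})

test_that("per-gene cross-misalignment matches its binomial rate", {
  cfg <- sim_config(seed = 33, n_genes = 400, n_homolog_pairs = 120,
                    n_droplets = c(human_singlet = 800), rho_fixed = 0,
                    qc_outlier_fraction = 0)
  sim <- simulate_dataset(cfg)
  m_cross <- sim$params$m_cross
  l <- sim$ledger
  gidx <- match(l$feature_id, sim$params$features$feature_id)
  # pick the most-expressed gene with a substantial rate
  cand <- which(m_cross > 0.2 & m_cross < 0.9)
  tot_by_gene <- tapply(l$n_matching, gidx, sum)
  cand <- cand[cand %in% as.integer(names(tot_by_gene))]
  g <- cand[which.max(tot_by_gene[as.character(cand)])]
  sel <- gidx == g
  n <- sum(l$n_matching[sel]); x <- sum(l$n_cross[sel])
  p <- m_cross[g]
  expect_gt(n, 100)
  expect_lt(abs(x / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("trap genes gain matching-view counts only through cross-species ambient", {
  base <- list(seed = 44, n_genes = 300, n_homolog_pairs = 90,
               n_droplets = c(human_singlet = 80, mouse_singlet = 80, empty = 40))
  tg <- trap_genes(do.call(sim_config, base))
  count_trap <- function(sim) {
    hs <- sim$truth$barcode[sim$truth$class == "human_singlet"]
    hv <- sim$human_view
    sum(hv$counts[match(tg$human, hv$features$feature_id),
                  match(hs, hv$barcodes)])
  }
  sim_off <- simulate_dataset(do.call(sim_config, c(base, list(rho_fixed = 0))))
  expect_identical(count_trap(sim_off), 0)
  sim_nocross <- simulate_dataset(do.call(sim_config, c(base, list(
    rho_fixed = 0.1, trap_m_cross = 0, m_cross_mean = 0, m_hot_frac = 0))))
  expect_identical(count_trap(sim_nocross), 0)
  sim_on <- simulate_dataset(do.call(sim_config, c(base, list(rho_fixed = 0.1))))
  expect_gt(count_trap(sim_on), 0)
})

test_that("a noiseless atlas equals the simulator's type profiles", {
  cfg <- small_config()
  atlas <- make_atlas(cfg)
  prm <- xdeconv:::sim_params(cfg)
  K <- cfg$n_cell_types
  expect_equal(unname(atlas$profiles[seq_len(cfg$n_genes), seq_len(K)]),
               unname(prm$profiles_human[, seq_len(K)]))
  expect_gte(sum(atlas$species == "human"), 1)
  expect_gte(sum(atlas$species == "mouse"), 1)
  expect_true(all(atlas$profiles >= 0))
})

test_that("pure cells correlate best with their own type's atlas profile", {
  sim <- small_sim()
  atlas <- small_atlas()
  hs <- sim$truth[sim$truth$class == "human_singlet", ]
  hs <- hs[seq_len(min(100, nrow(hs))), ]
  corr <- atlas_correlation(sim$combined, atlas, barcodes = hs$barcode)
  expect_gt(median(corr$best_corr_human), median(corr$best_corr_mouse))
})

test_that("expected_error_rate is a read-share weighted mean of misalignment", {
  cfg <- small_config()
  prm <- xdeconv:::sim_params(cfg)
  # independent recomputation from the realized parameters
  K <- prm$n_normal; qof <- cfg$qc_outlier_fraction
  wmix <- function(P) (1 - qof) * rowMeans(P[, 1:K, drop = FALSE]) +
    qof * rowMeans(P[, K + 1:K, drop = FALSE])
  w <- c(cfg$n_droplets[["human_singlet"]] * wmix(prm$profiles_human),
         cfg$n_droplets[["mouse_singlet"]] * wmix(prm$profiles_mouse))
  w <- w / sum(w)
  expect_equal(expected_error_rate(cfg), sum(w * (prm$m_cross + prm$m_multi)))
  # no misalignment at all: exactly zero
  cfg0 <- sim_config(seed = 2, n_genes = 200, n_homolog_pairs = 50,
                     m_cross_mean = 0, m_multi_mean = 0, m_hot_frac = 0,
                     n_trap_genes = 0,
                     n_droplets = c(human_singlet = 10, mouse_singlet = 10))
  expect_identical(expected_error_rate(cfg0), 0)
})

test_that("expected error grows monotonically with the misalignment scale", {
  errs <- vapply(c(0.05, 0.2, 0.5, 1), function(ms)
    expected_error_rate(small_config(m_scale = ms)), numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("dataset artifacts round-trip through disk", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  expect_true(all(file.exists(file.path(d, c("truth.tsv", "ledger.tsv",
                                             "composition.tsv")))))
  back <- read_tenx(file.path(d, "human"), view = "human")
  expect_identical(as.matrix(back$counts), as.matrix(sim$human_view$counts))
  tr <- read.delim(file.path(d, "truth.tsv"), stringsAsFactors = FALSE)
  expect_identical(tr$class, sim$truth$class)
})
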