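test_that("ambient profile is the normalized sum of sub-cap barcodes", {
  ft <- feature_table(c("gA", "gB"), c("HG1", "HG2"), "human")
  m <- CountMatrix(matrix(c(3, 1, 500, 500), nrow = 2), ft, c("empty", "cell"),
                   view = "human")
  amb <- estimate_ambient_profile(m, cap = 100)
  expect_equal(unname(amb$fractions), c(0.75, 0.25))
  expect_equal(amb$n_source_barcodes, 1)
  big <- CountMatrix(matrix(c(500, 500), nrow = 2), ft, "cell", view = "human")
  expect_error(estimate_ambient_profile(big, cap = 100),
               class = "xdeconv_integrity_error")
})

test_that("estimated ambient profile recovers the true pool", {
  sim <- small_sim()
  amb <- estimate_ambient_profile(sim$combined, cap = 100)
  # the combined view sees the origin pool through the read fates: thinned
  # by misalignment and multi-mapping, with crossed reads on the homolog
  prm <- sim$params
  e <- prm$pool * (1 - prm$m_cross - prm$m_multi)
  paired <- which(!is.na(prm$partner))
  e[prm$partner[paired]] <- e[prm$partner[paired]] +
    prm$pool[paired] * prm$m_cross[paired]
  expect_gt(cor(amb$fractions, e / sum(e)), 0.95)
})

test_that("prefilter applies the gene-count and mitochondrial rules", {
  G <- 300
  ft <- feature_table(
    feature_id = c(sprintf("h%03d", 1:G), sprintf("m%03d", 1:G)),
    feature_name = c("MT-1", sprintf("HG%d", 2:G), "mt-1", sprintf("mg%d", 2:G)),
    species = rep(c("human", "mouse"), each = G))
  mk_col <- function(h_genes, mito_frac = 0.02) {
    v <- numeric(2 * G)
    if (h_genes > 0) {
      per <- 500 %/% h_genes
      v[2:(h_genes + 1)] <- per
      v[1] <- round(mito_frac / (1 - mito_frac) * per * h_genes)
    }
    v
  }
  counts <- cbind(mk_col(250),              # keeps: 250 genes, 2% mito
                  mk_col(150),              # low_quality: 150 genes
                  mk_col(250, 0.05),        # removed: 5% mito vs 2% ambient
                  c(rep(1, 60), numeric(2 * G - 60)))  # empty-like (60 reads)
  m <- CountMatrix(counts, ft, paste0("bc", 1:4), "combined")
  ambient <- structure(list(fractions = rep(1 / (2 * G), 2 * G),
                            mito_pct = c(human = 2, mouse = 2),
                            n_source_barcodes = 5), class = "AmbientProfile")
  calls <- prefilter(m, ambient, min_genes = 200, mito_multiplier = 2, cap = 100)
  expect_identical(calls$label, c("pending", "low_quality", "low_quality", "empty_like"))
  expect_match(calls$reasons[2], "min_genes")
  expect_match(calls$reasons[3], "mito_vs_ambient")
  # one species >= 200 genes is enough even if the other has none
  expect_identical(calls$label[1], "pending")
})

test_that("a barcode matching an atlas profile correlates at exactly 1", {
  cfg <- small_config()
  atlas <- small_atlas()
  prm <- xdeconv:::sim_params(cfg)
  prof <- round(atlas$profiles[, 1] * 1e5)  # a scaled copy of human type 1
  counts <- cbind(prof, numeric(length(prof)))
  m <- CountMatrix(counts, prm$features, c("copy", "zero"), "combined")
  corr <- atlas_correlation(m, atlas)
  expect_equal(corr$best_corr_human[1], 1, tolerance = 1e-3)
  # the all-zero barcode hits the constant-vector convention
  expect_identical(corr$best_corr_human[2], 0)
  expect_identical(corr$best_corr_mouse[2], 0)
})

test_that("simulated human cells separate from mouse cells on both axes", {
  sim <- small_sim()
  atlas <- small_atlas()
  tt <- sim$truth
  bcs <- tt$barcode[tt$class %in% c("human_singlet", "mouse_singlet")]
  corr <- atlas_correlation(sim$combined, atlas, barcodes = bcs)
  cls <- tt$class[match(corr$barcode, tt$barcode)]
  expect_gt(median(corr$best_corr_human[cls == "human_singlet"]),
            median(corr$best_corr_human[cls == "mouse_singlet"]) + 0.3)
  expect_gt(median(corr$best_corr_mouse[cls == "mouse_singlet"]),
            median(corr$best_corr_mouse[cls == "human_singlet"]) + 0.3)
})

test_that("cutoffs degenerate correctly and match an order-statistic oracle", {
  mk_corr <- function(h, m) {
    structure(data.frame(barcode = paste0("b", seq_along(h)),
                         best_corr_human = h, best_corr_mouse = m,
                         norm_corr_human = h, norm_corr_mouse = m),
              class = c("CorrelationResult", "data.frame"))
  }
  # identical values: cutoff equals that value under both methods
  v <- rep(0.8, 40)
  corr <- mk_corr(v, v)
  maj <- rep(c("human", "mouse"), each = 20)
  expect_equal(compute_cutoffs(corr, maj, method = "mad")$cutoff_human, 0.8)
  expect_equal(compute_cutoffs(corr, maj, method = "median_ci")$cutoff_human, 0.8)

  # n = 100 draws from a known distribution: the median_ci cutoff is the
  # order statistic at rank floor((n - z*sqrt(n))/2), computed by brute force
  set.seed(5)
  x <- rbeta(100, 5, 2)
  corr2 <- mk_corr(c(x, runif(30)), c(runif(100), rbeta(30, 5, 2)))
  maj2 <- rep(c("human", "mouse"), c(100, 30))
  got <- compute_cutoffs(corr2, maj2, method = "median_ci")$cutoff_human
  rank_expect <- floor((100 - qnorm(0.995) * sqrt(100)) / 2)
  expect_identical(got, sort(x)[rank_expect])

  # adding barcodes to the other species' group leaves the cutoff unchanged
  corr3 <- mk_corr(c(x, runif(60)), c(runif(100), rbeta(60, 5, 2)))
  maj3 <- rep(c("human", "mouse"), c(100, 60))
  expect_identical(compute_cutoffs(corr3, maj3, method = "median_ci")$cutoff_human, got)
  expect_identical(compute_cutoffs(corr3, maj3)$cutoff_human,
                   compute_cutoffs(corr2, maj2)$cutoff_human)
})

test_that("classification rules fire in order", {
  calls <- xdeconv:::new_species_call(paste0("b", 1:4),
                                      c("human", "human", "human", "mouse"))
  corr <- structure(data.frame(
    barcode = paste0("b", 1:4),
    best_corr_human = c(0.9, 0.3, 0.9, 0.2),
    best_corr_mouse = c(0.85, 0.8, 0.2, 0.9),
    norm_corr_human = c(0.95, 0.3, 0.9, 0.1),
    norm_corr_mouse = c(0.9, 0.85, 0.2, 0.95)),
    class = c("CorrelationResult", "data.frame"))
  cut <- structure(list(cutoff_human = 0.6, cutoff_mouse = 0.6, method = "mad"),
                   class = "SpeciesCutoffs")
  out <- classify_barcodes(calls, corr, cut)
  expect_identical(out$label, c("cross_doublet", "discrepant", "human", "mouse"))
  expect_match(out$reasons[1], "high_corr_both")
  expect_match(out$reasons[2], "majority_corr_mismatch")
})

test_that("cluster minority removal relabels minority species in pure clusters", {
  sim <- small_sim()
  run <- small_run()
  calls <- run$calls
  # plant: five human-called cells relabelled mouse inside a human cluster
  sc <- call_species(sim$combined, small_atlas(), pipeline_config(seed = 7))
  calls <- sc$calls
  hum <- which(calls$label == "human")
  planted <- hum[1:5]
  calls$label[planted] <- "mouse"
  out <- cluster_minority_removal(sim$combined, calls, seed = 3)
  expect_true(out$separated)
  expect_true(all(out$calls$label[planted] == "discrepant"))
  # a clustering that is already pure changes nothing
  out2 <- cluster_minority_removal(sim$combined, sc$calls, seed = 3)
  n_flip <- sum(out2$calls$label != sc$calls$label)
  expect_lte(n_flip, round(0.01 * nrow(calls)))
})

test_that("cnv score separates planted aneuploid cells and gates on genes", {
  cfg <- sim_config(seed = 9, n_genes = 2000, n_homolog_pairs = 600,
                    n_cell_types = 4, tumor_fraction = 0.3,
                    n_droplets = c(human_singlet = 700, empty = 150))
  sim <- simulate_dataset(cfg)
  hv <- split_by_species(sim$combined)$human
  hs <- sim$truth$barcode[sim$truth$class == "human_singlet"]
  cv <- cnv_score(hv, barcodes = hs, seed = 3)
  tt <- sim$truth[match(cv$barcode, sim$truth$barcode), ]
  expect_gt(auroc(cv$score, tt$aneuploid), 0.95)
  # a homogeneous diploid population yields no aneuploid calls
  dip <- cnv_score(hv, barcodes = hs[!tt$aneuploid][1:300], seed = 3)
  expect_identical(sum(dip$ploidy == "aneuploid"), 0L)
  # too few expressed genes: not assessable
  few <- hv
  few$counts[, 1] <- 0
  few$counts[1:10, 1] <- 1
  cv2 <- cnv_score(few, barcodes = few$barcodes[1], seed = 3)
  expect_identical(cv2$ploidy, "not_assessable")
})

test_that("tumour rules rescue aneuploid human cells and flag mouse-majority", {
  calls <- xdeconv:::new_species_call(paste0("b", 1:4),
                                      c("human", "mouse", "mouse", "human"))
  calls$label <- c("discrepant", "mouse", "mouse", "low_quality")
  cnv <- structure(data.frame(
    barcode = paste0("b", 1:4), score = c(5, 1, 1, 5),
    ploidy = c("aneuploid", "diploid", "not_assessable", "aneuploid")),
    class = c("CnvResult", "data.frame"))
  out <- apply_tumor_rules(calls, cnv)
  expect_identical(out$label[1], "human")          # tumour rescue
  expect_match(out$reasons[1], "tumor_rescue")
  expect_identical(out$label[2], "cross_doublet")  # valid CNV + mouse majority
  expect_identical(out$label[3], "mouse")          # not assessable: unchanged
  expect_identical(out$label[4], "low_quality")    # prefiltered stays out
})
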