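# Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a small but complete barnyard library (all droplet classes, ambient,
# traps, misalignment) used by most module tests
small_config <- function(seed = 11, ...) {
  sim_config(seed = seed,
             n_genes = 800L, n_homolog_pairs = 240L,
             n_droplets = c(human_singlet = 450, mouse_singlet = 450,
                            cross_doublet = 60, intrasample_doublet = 60,
                            intersample_doublet = 30, empty = 400),
             ...)
}

small_sim <- function() memo("small_sim", simulate_dataset(small_config()))
small_atlas <- function() memo("small_atlas", make_atlas(small_config()))

small_run <- function() memo("small_run", {
  sim <- small_sim()
  suppressWarnings(run_pipeline(
    sim$combined, sim$human_view, sim$mouse_view, small_atlas(),
    assignment = assignment_from_truth(sim$truth),
    config = pipeline_config(seed = 7)))
})

# hand-built toy combined matrix: 2 human genes (one mito) + 2 mouse genes
# (one mito), 4 barcodes
toy_combined <- function() {
  ft <- feature_table(
    feature_id = c("hA", "hMT", "mA", "mMT"),
    feature_name = c("HGENE1", "MT-H1", "mgene1", "mt-m1"),
    species = c("human", "human", "mouse", "mouse"))
  counts <- matrix(c(15, 5, 0, 0,    # bc1: pure human, 25% mito
                     0, 0, 18, 2,    # bc2: pure mouse, 10% mito
                     10, 0, 10, 0,   # bc3: mixed
                     0, 0, 0, 0),    # bc4: empty
                   nrow = 4, dimnames = NULL)
  CountMatrix(counts, ft, paste0("bc", 1:4), view = "combined")
}

# default-scale simulation + pipeline run shared by the acceptance tests
default_sim <- function(seed = 1) {
  memo(paste0("default_sim_", seed), simulate_dataset(sim_config(seed = seed)))
}

default_run <- function(seed = 1) {
  memo(paste0("default_run_", seed), {
    sim <- default_sim(seed)
    suppressWarnings(run_pipeline(
      sim$combined, sim$human_view, sim$mouse_view,
      make_atlas(sim_config(seed = seed)),
      assignment = assignment_from_truth(sim$truth),
      config = pipeline_config(seed = seed + 100L)))
  })
}

auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
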