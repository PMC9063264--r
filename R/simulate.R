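# Generative barnyard simulator.
#
# Emits the combined-reference view and both species-matching views of the
# same droplets, together with an exact per-read fate ledger. Reads are
# drawn per droplet: library size is log-normal, a Beta-distributed ambient
# fraction rho of reads comes from a shared two-species ambient pool, and
# the rest from the member cells' type profiles (Dirichlet gene
# probabilities). Each read of origin gene g is then cross-misaligned to
# the homolog of the other species with probability m_cross(g), excluded as
# an exonic multi-mapper with probability m_multi(g), and otherwise counted
# correctly. The same fate draw feeds every view, so the bookkeeping
# identity n_matching = n_correct + n_cross + n_multi is exact per
# (barcode, origin gene).

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_dataset()]. Defaults give
#' a 10,000-droplet, 4,000-gene barnyard library: 5% cross-species
#' doublets, mean ambient contamination 0.05, empty droplets under 100
#' reads, per-gene cross-misalignment averaging ~0.5% with a small set of
#' strongly misaligning homologs, and per species a handful of "trap"
#' genes with zero own-species expression whose other-species homolog is
#' highly expressed — the mechanism by which cross-species ambient RNA
#' creates false signal in a species-matching reference.
#'
#' @param seed integer RNG seed; the whole dataset is deterministic given it.
#' @param n_genes genes per species.
#' @param n_homolog_pairs human-mouse homolog pairs (only paired genes can
#'   cross-misalign or multi-map).
#' @param n_cell_types cell types per species.
#' @param n_samples named integer vector, pooled samples per species.
#' @param n_droplets named integer vector of droplet class counts
#'   (`human_singlet`, `mouse_singlet`, `cross_doublet`,
#'   `intrasample_doublet`, `intersample_doublet`, `empty`).
#' @param lib_meanlog,lib_sdlog log-normal library size of a cell.
#' @param empty_meanlog,empty_sdlog log-normal library size of an empty
#'   droplet, truncated below `empty_cap` reads.
#' @param empty_cap empty droplets never reach this many reads.
#' @param dirichlet_alpha symmetric Dirichlet concentration of cell-type
#'   gene-probability profiles (small values give sparse, well-separated
#'   types).
#' @param rho_shape Beta(a, b) parameters of the per-droplet ambient
#'   fraction; the default mean is 0.05.
#' @param rho_fixed if non-`NULL`, a fixed ambient fraction overriding
#'   `rho_shape`.
#' @param n_mito mitochondrial genes per species.
#' @param mito_fraction expression mass on mitochondrial genes per profile.
#' @param n_trap_genes ambient-trap homolog pairs per direction.
#' @param trap_expression expression mass of each hot trap homolog in the
#'   other species' profiles.
#' @param trap_m_cross cross-misalignment probability of a hot trap homolog.
#' @param m_cross_mean,m_multi_mean mean per-gene cross-misalignment /
#'   exonic multi-mapping probability of ordinary homolog pairs.
#' @param m_hot_frac,m_hot_range fraction of homolog pairs given a large
#'   cross-misalignment probability, uniform on `m_hot_range`.
#' @param m_scale scalar multiplier on all misalignment probabilities
#'   (used to sweep the expected combined-reference error).
#' @param tumor_fraction fraction of cells of human sample `tumor_sample`
#'   that are aneuploid.
#' @param tumor_sample index of the human sample carrying tumour cells.
#' @param cnv_n_blocks,cnv_genome_frac,cnv_folds copy-number blocks of the
#'   aneuploid expression profiles: number of contiguous genomic blocks,
#'   total fraction of the genome covered, alternating fold changes.
#' @param qc_outlier_fraction fraction of singlets drawn from a high-
#'   mitochondrial variant of their type profile (quality-filter fodder).
#' @param qc_outlier_mito mitochondrial mass of those variants.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_homolog_pairs = 600L,
                       n_cell_types = 4L,
                       n_samples = c(human = 2L, mouse = 2L),
                       n_droplets = c(human_singlet = 3150L, mouse_singlet = 3150L,
                                      cross_doublet = 500L, intrasample_doublet = 550L,
                                      intersample_doublet = 250L, empty = 2400L),
                       lib_meanlog = log(2500), lib_sdlog = 0.35,
                       empty_meanlog = log(40), empty_sdlog = 0.7,
                       empty_cap = 100L,
                       dirichlet_alpha = 0.3,
                       rho_shape = c(2, 38), rho_fixed = NULL,
                       n_mito = 13L, mito_fraction = 0.05,
                       n_trap_genes = 3L, trap_expression = 0.02, trap_m_cross = 0.8,
                       m_cross_mean = 0.005, m_multi_mean = 0.003,
                       m_hot_frac = 0.05, m_hot_range = c(0.2, 0.6),
                       m_scale = 1,
                       tumor_fraction = 0, tumor_sample = 1L,
                       cnv_n_blocks = 5L, cnv_genome_frac = 0.30,
                       cnv_folds = c(2, 0.5),
                       qc_outlier_fraction = 0.02, qc_outlier_mito = 0.25) {
  cfg <- as.list(environment())
  class_names <- c("human_singlet", "mouse_singlet", "cross_doublet",
                   "intrasample_doublet", "intersample_doublet", "empty")
  nd <- integer(6); names(nd) <- class_names
  nd[names(n_droplets)] <- as.integer(n_droplets)
  cfg$n_droplets <- nd
  ns <- c(human = 1L, mouse = 1L)
  ns[names(n_samples)] <- as.integer(n_samples)
  cfg$n_samples <- ns
  stopifnot(n_genes >= 20, n_homolog_pairs >= 0,
            n_homolog_pairs <= n_genes - n_mito,
            2 * n_trap_genes <= n_homolog_pairs || n_trap_genes == 0,
            all(nd >= 0), sum(nd) > 0,
            n_cell_types >= 1, n_mito >= 1, empty_cap > 1)
  for (p in c("dirichlet_alpha")) stopifnot(cfg[[p]] > 0)
  for (p in c("mito_fraction", "trap_expression", "trap_m_cross", "m_cross_mean",
              "m_multi_mean", "m_hot_frac", "tumor_fraction",
              "qc_outlier_fraction", "qc_outlier_mito", "cnv_genome_frac")) {
    v <- cfg[[p]]
    if (any(v < 0) || any(v > 1)) stop_integrity(p, " must lie in [0, 1]")
  }
  if (!is.null(rho_fixed) && (rho_fixed < 0 || rho_fixed > 1))
    stop_integrity("rho_fixed must lie in [0, 1]")
  if (nd["intersample_doublet"] > 0 && max(ns) < 2)
    stop_integrity("intersample doublets need a species with >= 2 samples")
  structure(cfg, class = "sim_config")
}

# deterministic gene-level parameters and expression profiles; consumes the
# head of the seeded RNG stream, so simulate_dataset() continues after it
sim_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; K <- config$n_cell_types
  nm <- config$n_mito; np <- config$n_homolog_pairs; nt <- config$n_trap_genes

  mito_idx <- (G - nm + 1L):G                   # per-species local indices
  pair_idx <- seq_len(np)                       # gene i pairs with gene i
  trap_h <- if (nt) seq_len(nt) else integer(0)            # human gene 0, mouse homolog hot
  trap_m <- if (nt) nt + seq_len(nt) else integer(0)       # mouse gene 0, human homolog hot

  features <- feature_table(
    feature_id = c(sprintf("hG%04d", seq_len(G)), sprintf("mG%04d", seq_len(G))),
    feature_name = c(ifelse(seq_len(G) %in% mito_idx,
                            sprintf("MT-H%02d", seq_len(G) - G + nm),
                            sprintf("HGENE%04d", seq_len(G))),
                     ifelse(seq_len(G) %in% mito_idx,
                            sprintf("mt-m%02d", seq_len(G) - G + nm),
                            sprintf("mgene%04d", seq_len(G)))),
    species = rep(c("human", "mouse"), each = G),
    chromosome = NA_character_,
    genomic_index = c(sample.int(G), sample.int(G)),
    homolog_id = c(ifelse(seq_len(G) %in% pair_idx, sprintf("HOM%04d", seq_len(G)), NA),
                   ifelse(seq_len(G) %in% pair_idx, sprintf("HOM%04d", seq_len(G)), NA))
  )
  # combined-space partner index (NA for unpaired genes)
  partner <- rep(NA_integer_, 2L * G)
  partner[pair_idx] <- G + pair_idx
  partner[G + pair_idx] <- pair_idx

  # per-gene misalignment probabilities on the combined space
  draw_m <- function(mean) {
    m <- numeric(2L * G)
    if (np && mean > 0) {
      b <- max(1 / mean - 1, 1e-6)
      m[pair_idx] <- rbeta(np, 1, b)
      m[G + pair_idx] <- rbeta(np, 1, b)
    }
    m
  }
  m_cross <- draw_m(config$m_cross_mean)
  m_multi <- draw_m(config$m_multi_mean)
  if (np && config$m_hot_frac > 0) {
    n_hot <- max(0L, round(config$m_hot_frac * np))
    if (n_hot) {
      hot_h <- sample(setdiff(pair_idx, c(trap_h, trap_m)), min(n_hot, np - 2 * nt))
      hot_m <- G + sample(setdiff(pair_idx, c(trap_h, trap_m)), min(n_hot, np - 2 * nt))
      m_cross[hot_h] <- runif(length(hot_h), config$m_hot_range[1], config$m_hot_range[2])
      m_cross[hot_m] <- runif(length(hot_m), config$m_hot_range[1], config$m_hot_range[2])
    }
  }
  # hot trap homologs: mouse partner of a human trap, human partner of a mouse trap
  m_cross[G + trap_h] <- config$trap_m_cross
  m_cross[trap_m] <- config$trap_m_cross
  m_cross <- pmin(m_cross * config$m_scale, 0.95)
  m_multi <- pmin(m_multi * config$m_scale, 0.95)
  sq <- m_cross + m_multi
  over <- sq > 1
  if (any(over)) m_multi[over] <- 1 - m_cross[over]

  # expression profiles per species: genes x profiles. Profile catalogue:
  # 1..K normal types, K+1..2K high-mito variants, (human) 2K+1..3K aneuploid.
  base_profile <- function(own_zero, own_hot) {
    p <- rgamma(G, shape = config$dirichlet_alpha)
    p[mito_idx] <- 0; p[own_zero] <- 0; p[own_hot] <- 0
    if (sum(p) == 0) p[seq_len(G - nm)] <- 1
    free_mass <- 1 - config$mito_fraction - length(own_hot) * config$trap_expression
    p <- p / sum(p) * free_mass
    p[mito_idx] <- config$mito_fraction / nm
    p[own_hot] <- config$trap_expression
    p
  }
  reprofile_mito <- function(p, frac) {
    q <- p; q[mito_idx] <- 0
    q <- q / sum(q) * (1 - frac)
    q[mito_idx] <- frac / nm
    q
  }
  # human profiles: own traps zero, partners of mouse traps hot
  human_norm <- vapply(seq_len(K), function(i) base_profile(trap_h, trap_m), numeric(G))
  mouse_norm <- vapply(seq_len(K), function(i) base_profile(trap_m, trap_h), numeric(G))
  human_out <- apply(human_norm, 2, reprofile_mito, frac = config$qc_outlier_mito)
  mouse_out <- apply(mouse_norm, 2, reprofile_mito, frac = config$qc_outlier_mito)

  # aneuploid variants: fold changes on contiguous genomic_index blocks
  cnv_blocks <- NULL
  human_tum <- NULL
  if (config$tumor_fraction > 0 && config$cnv_n_blocks > 0) {
    nb <- config$cnv_n_blocks
    block_len <- max(1L, floor(config$cnv_genome_frac * G / nb))
    gap <- floor(G / nb)
    starts <- (seq_len(nb) - 1L) * gap + 1L
    folds <- rep_len(config$cnv_folds, nb)
    cnv_blocks <- data.frame(start = starts, end = pmin(starts + block_len - 1L, G),
                             fold = folds)
    gidx_h <- features$genomic_index[seq_len(G)]
    fold_vec <- rep(1, G)
    for (b in seq_len(nb))
      fold_vec[gidx_h >= cnv_blocks$start[b] & gidx_h <= cnv_blocks$end[b]] <- cnv_blocks$fold[b]
    human_tum <- apply(human_norm, 2, function(p) { q <- p * fold_vec; q / sum(q) })
  }
  P_h <- cbind(human_norm, human_out, human_tum)
  P_m <- cbind(mouse_norm, mouse_out)

  # ambient pool over the combined gene space: equal mix of all normal types,
  # species weighted equally
  pool <- c(rowMeans(human_norm), rowMeans(mouse_norm)) / 2

  list(features = features, partner = partner,
       m_cross = m_cross, m_multi = m_multi,
       profiles_human = P_h, profiles_mouse = P_m,
       n_normal = K, pool = pool,
       mito_idx = mito_idx, pair_idx = pair_idx,
       trap_human = trap_h, trap_mouse = trap_m,
       cnv_blocks = cnv_blocks)
}

#' Genes acting as cross-species ambient traps
#'
#' Returns the feature ids of genes that have zero own-species expression in
#' every simulated cell type while their homolog in the other species is
#' highly expressed: any count they acquire in a species-matching view must
#' have entered the droplet as other-species ambient RNA and cross-misaligned.
#'
#' @param config a [sim_config()].
#' @return A list with character vectors `human` and `mouse` (trap genes of
#'   each species' own genome).
#' @export
trap_genes <- function(config) {
  p <- sim_params(config)
  G <- config$n_genes
  list(human = p$features$feature_id[p$trap_human],
       mouse = p$features$feature_id[G + p$trap_mouse])
}

#' Simulate a barnyard dataset with ground truth and a read-fate ledger
#'
#' Generates one droplet library under `config` and returns three views of
#' it: the combined two-species reference (cross-misaligned reads counted to
#' the other species' homolog, multi-mappers counted to nothing) and the two
#' species-matching references (every read of that species' origin counted
#' to its true gene; other-species reads counted to their homolog exactly
#' when they cross-misaligned). All three views share the same barcodes.
#'
#' @param config a [sim_config()].
#' @return A list of class `xdeconv_sim`:
#' \describe{
#'   \item{combined, human_view, mouse_view}{[CountMatrix()] views.}
#'   \item{truth}{per-barcode `data.frame`: `class`, `species`, `sample_id`,
#'     `cell_type` (plus `sample_id2`/`cell_type2` for doublets), true
#'     ambient fraction `rho`, `aneuploid`, `qc_outlier`.}
#'   \item{ledger}{`data.table` per (barcode, origin gene): `n_correct`,
#'     `n_cross`, `n_multi`, `n_matching` with
#'     `n_matching == n_correct + n_cross + n_multi` exactly.}
#'   \item{composition}{per-barcode cell/ambient read totals by species.}
#'   \item{params}{realised gene-level parameters (see `sim_params`).}
#' }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prm <- sim_params(config)     # seeds the stream and consumes its head
  G <- config$n_genes; K <- config$n_cell_types
  nd <- config$n_droplets; n_total <- sum(nd)
  ns <- config$n_samples

  classes <- sample(rep(names(nd), nd))
  barcodes <- sprintf("BC%05d-1", seq_len(n_total))

  pick_species <- function(n) sample(c("human", "mouse"), n, replace = TRUE)
  pick_type <- function(n) sample.int(K, n, replace = TRUE)
  pick_sample <- function(sp, n) vapply(sp, function(s) sample.int(ns[[s]], 1L), 1L)

  # truth scaffold
  tr <- data.frame(barcode = barcodes, class = classes,
                   species = NA_character_, sample_id = NA_character_,
                   cell_type = NA_character_, sample_id2 = NA_character_,
                   cell_type2 = NA_character_, rho = 0,
                   aneuploid = FALSE, qc_outlier = FALSE,
                   stringsAsFactors = FALSE)

  rho_draw <- function(n) {
    if (!is.null(config$rho_fixed)) rep(config$rho_fixed, n)
    else rbeta(n, config$rho_shape[1], config$rho_shape[2])
  }
  lib_draw <- function(n) pmax(1L, as.integer(round(rlnorm(n, config$lib_meanlog, config$lib_sdlog))))
  empty_draw <- function(n) {
    x <- as.integer(round(rlnorm(n, config$empty_meanlog, config$empty_sdlog)))
    pmin(pmax(x, 1L), config$empty_cap - 1L)
  }
  type_label <- function(sp, t) sprintf("%s_type%d", sp, t)
  samp_label <- function(sp, s) sprintf("%s%d", substr(sp, 1, 1), s)
  # profile column for a member: outlier variants sit at K+type, tumour at 2K+type
  prof_col <- function(t, outlier, aneup) t + K * outlier + 2L * K * aneup

  # per-droplet member descriptors
  memb_sp <- vector("list", n_total); memb_col <- vector("list", n_total)
  memb_w <- vector("list", n_total)
  N <- integer(n_total)

  for (i in seq_len(n_total)) {
    cl <- classes[i]
    if (cl == "empty") {
      N[i] <- empty_draw(1L); tr$rho[i] <- 1
      memb_sp[[i]] <- character(0); memb_col[[i]] <- integer(0); memb_w[[i]] <- numeric(0)
      next
    }
    tr$rho[i] <- rho_draw(1L)
    if (cl %in% c("human_singlet", "mouse_singlet")) {
      sp <- if (cl == "human_singlet") "human" else "mouse"
      t <- pick_type(1L); s <- pick_sample(sp, 1L)
      outl <- runif(1) < config$qc_outlier_fraction
      aneu <- sp == "human" && s == config$tumor_sample &&
        runif(1) < config$tumor_fraction
      N[i] <- lib_draw(1L)
      tr$species[i] <- sp; tr$sample_id[i] <- samp_label(sp, s)
      tr$cell_type[i] <- type_label(sp, t)
      tr$aneuploid[i] <- aneu; tr$qc_outlier[i] <- outl
      memb_sp[[i]] <- sp
      memb_col[[i]] <- prof_col(t, outl && !aneu, aneu)
      memb_w[[i]] <- 1
    } else if (cl == "cross_doublet") {
      th <- pick_type(1L); tm <- pick_type(1L)
      sh <- pick_sample("human", 1L); sm <- pick_sample("mouse", 1L)
      aneu <- sh == config$tumor_sample && runif(1) < config$tumor_fraction
      l <- lib_draw(2L); N[i] <- sum(l)
      tr$species[i] <- "mixed"
      tr$sample_id[i] <- samp_label("human", sh); tr$cell_type[i] <- type_label("human", th)
      tr$sample_id2[i] <- samp_label("mouse", sm); tr$cell_type2[i] <- type_label("mouse", tm)
      tr$aneuploid[i] <- aneu
      memb_sp[[i]] <- c("human", "mouse")
      memb_col[[i]] <- c(prof_col(th, FALSE, aneu), prof_col(tm, FALSE, FALSE))
      memb_w[[i]] <- l / sum(l)
    } else {
      sp <- pick_species(1L)
      if (cl == "intersample_doublet" && ns[[sp]] < 2)
        sp <- names(ns)[which.max(ns)]
      t1 <- pick_type(1L); t2 <- pick_type(1L)
      if (cl == "intrasample_doublet") {
        s1 <- pick_sample(sp, 1L); s2 <- s1
      } else {
        ss <- sample.int(ns[[sp]], 2L); s1 <- ss[1]; s2 <- ss[2]
      }
      aneu1 <- sp == "human" && s1 == config$tumor_sample && runif(1) < config$tumor_fraction
      aneu2 <- sp == "human" && s2 == config$tumor_sample && runif(1) < config$tumor_fraction
      l <- lib_draw(2L); N[i] <- sum(l)
      tr$species[i] <- sp
      tr$sample_id[i] <- samp_label(sp, s1); tr$cell_type[i] <- type_label(sp, t1)
      tr$sample_id2[i] <- samp_label(sp, s2); tr$cell_type2[i] <- type_label(sp, t2)
      tr$aneuploid[i] <- aneu1 || aneu2
      memb_sp[[i]] <- c(sp, sp)
      memb_col[[i]] <- c(prof_col(t1, FALSE, aneu1), prof_col(t2, FALSE, aneu2))
      memb_w[[i]] <- l / sum(l)
    }
  }

  # read generation: origin-gene triplets on the combined gene space
  i_acc <- vector("list", 4L * n_total); g_acc <- i_acc; x_acc <- i_acc
  slot <- 0L
  comp <- matrix(0L, n_total, 4,
                 dimnames = list(NULL, c("cell_reads_human", "cell_reads_mouse",
                                         "ambient_reads_human", "ambient_reads_mouse")))
  P <- list(human = prm$profiles_human, mouse = prm$profiles_mouse)
  off <- c(human = 0L, mouse = G)

  push <- function(d, genes, counts) {
    slot <<- slot + 1L
    i_acc[[slot]] <<- rep.int(d, length(genes))
    g_acc[[slot]] <<- genes
    x_acc[[slot]] <<- counts
  }

  for (i in seq_len(n_total)) {
    n_amb <- rbinom(1L, N[i], tr$rho[i])
    n_cell <- N[i] - n_amb
    sps <- memb_sp[[i]]
    if (length(sps) && n_cell > 0) {
      w <- memb_w[[i]]
      n_m <- if (length(sps) == 1L) n_cell else {
        a <- rbinom(1L, n_cell, w[1]); c(a, n_cell - a)
      }
      for (j in seq_along(sps)) {
        if (n_m[j] == 0L) next
        x <- rmultinom(1L, n_m[j], P[[sps[j]]][, memb_col[[i]][j]])[, 1]
        nz <- which(x > 0L)
        push(i, nz + off[[sps[j]]], x[nz])
        comp[i, paste0("cell_reads_", sps[j])] <-
          comp[i, paste0("cell_reads_", sps[j])] + n_m[j]
      }
    }
    if (n_amb > 0L) {
      x <- rmultinom(1L, n_amb, prm$pool)[, 1]
      nz <- which(x > 0L)
      push(i, nz, x[nz])
      comp[i, "ambient_reads_human"] <- sum(x[seq_len(G)])
      comp[i, "ambient_reads_mouse"] <- n_amb - comp[i, "ambient_reads_human"]
    }
  }

  dt <- data.table::data.table(bc = unlist(i_acc[seq_len(slot)]),
                               gene = unlist(g_acc[seq_len(slot)]),
                               x = unlist(x_acc[seq_len(slot)]))
  dt <- dt[, list(x = sum(x)), by = c("bc", "gene")]
  data.table::setorderv(dt, c("bc", "gene"))

  # read fates by multinomial thinning, one draw reused by every view
  mc <- prm$m_cross[dt$gene]; mm <- prm$m_multi[dt$gene]
  dt$n_cross <- rbinom(nrow(dt), dt$x, mc)
  rem <- dt$x - dt$n_cross
  p2 <- ifelse(mc < 1, mm / (1 - mc), 0)
  dt$n_multi <- rbinom(nrow(dt), rem, p2)
  dt$n_correct <- rem - dt$n_multi

  prt <- prm$partner[dt$gene]
  has_cross <- dt$n_cross > 0L

  make_mat <- function(i, j, x) {
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(2L * G, n_total))
  }
  combined_m <- make_mat(c(dt$gene, prt[has_cross]),
                         c(dt$bc, dt$bc[has_cross]),
                         c(dt$n_correct, dt$n_cross[has_cross]))

  is_h <- dt$gene <= G
  # human view: all human-origin reads at their gene + mouse-origin crossed
  # reads at their (human) homolog
  hm_src <- has_cross & !is_h
  human_full <- make_mat(c(dt$gene[is_h], prt[hm_src]),
                         c(dt$bc[is_h], dt$bc[hm_src]),
                         c(dt$x[is_h], dt$n_cross[hm_src]))
  mh_src <- has_cross & is_h
  mouse_full <- make_mat(c(dt$gene[!is_h], prt[mh_src]),
                         c(dt$bc[!is_h], dt$bc[mh_src]),
                         c(dt$x[!is_h], dt$n_cross[mh_src]))

  ft <- prm$features
  h_rows <- seq_len(G); m_rows <- G + seq_len(G)
  ft_h <- ft[h_rows, , drop = FALSE]; rownames(ft_h) <- NULL
  ft_m <- ft[m_rows, , drop = FALSE]; rownames(ft_m) <- NULL

  combined <- CountMatrix(combined_m, ft, barcodes, view = "combined")
  human_view <- CountMatrix(human_full[h_rows, , drop = FALSE], ft_h, barcodes, view = "human")
  mouse_view <- CountMatrix(mouse_full[m_rows, , drop = FALSE], ft_m, barcodes, view = "mouse")

  ledger <- data.table::data.table(
    barcode = barcodes[dt$bc],
    feature_id = ft$feature_id[dt$gene],
    origin_species = ifelse(is_h, "human", "mouse"),
    n_correct = dt$n_correct, n_cross = dt$n_cross,
    n_multi = dt$n_multi, n_matching = dt$x)

  structure(list(combined = combined, human_view = human_view,
                 mouse_view = mouse_view, truth = tr,
                 ledger = ledger,
                 composition = data.frame(barcode = barcodes, comp,
                                          stringsAsFactors = FALSE),
                 params = prm, config = config),
            class = "xdeconv_sim")
}

#' @export
print.xdeconv_sim <- function(x, ...) {
  cat(sprintf("Simulated barnyard library: %d droplets, %d+%d genes, %.0f reads\n",
              length(x$combined$barcodes), x$config$n_genes, x$config$n_genes,
              sum(x$ledger$n_matching)))
  print(table(x$truth$class))
  invisible(x)
}

#' Build a reference expression atlas from the simulator's type profiles
#'
#' Returns per-cell-type mean expression profiles on the combined gene
#' space, one per (species, cell type), optionally perturbed by
#' multiplicative log-normal noise. This plays the role an external
#' reference atlas of cell-type expression plays for real data.
#'
#' @param config a [sim_config()].
#' @param noise_sd standard deviation of log-normal multiplicative noise
#'   (0 returns the exact simulator profiles).
#' @return An object of class `ReferenceAtlas`: list with `profiles`
#'   (genes x profiles matrix, columns sum to 1), `species` per profile and
#'   `feature_id` rownames.
#' @export
make_atlas <- function(config, noise_sd = 0) {
  prm <- sim_params(config)
  G <- config$n_genes; K <- prm$n_normal
  H <- prm$profiles_human[, seq_len(K), drop = FALSE]
  M <- prm$profiles_mouse[, seq_len(K), drop = FALSE]
  prof <- rbind(cbind(H, matrix(0, G, K)),
                cbind(matrix(0, G, K), M))
  colnames(prof) <- c(sprintf("human_type%d", seq_len(K)),
                      sprintf("mouse_type%d", seq_len(K)))
  rownames(prof) <- prm$features$feature_id
  if (noise_sd > 0) {
    set.seed(config$seed + 7919L)
    prof <- prof * matrix(rlnorm(length(prof), 0, noise_sd), nrow(prof))
    prof <- sweep(prof, 2, colSums(prof), "/")
  }
  structure(list(profiles = prof,
                 species = rep(c("human", "mouse"), each = K),
                 feature_id = prm$features$feature_id),
            class = "ReferenceAtlas")
}

#' @export
print.ReferenceAtlas <- function(x, ...) {
  cat(sprintf("ReferenceAtlas: %d profiles (%d human, %d mouse) on %d genes\n",
              ncol(x$profiles), sum(x$species == "human"),
              sum(x$species == "mouse"), nrow(x$profiles)))
  invisible(x)
}

#' Expected combined-reference error rate of a configuration
#'
#' Closed-form expectation of the combined-reference error (cross-misaligned
#' reads plus the multi-mapping increment over total matching-reference
#' reads) under a singlet-only, ambient-free configuration: the read-share
#' weighted mean of `m_cross(g) + m_multi(g)`. For configurations with
#' ambient or doublets this is the cell-origin component only.
#'
#' @param config a [sim_config()].
#' @return Expected error as a fraction.
#' @export
expected_error_rate <- function(config) {
  prm <- sim_params(config)
  G <- config$n_genes; K <- prm$n_normal
  qof <- config$qc_outlier_fraction
  mix <- function(P) (1 - qof) * rowMeans(P[, seq_len(K), drop = FALSE]) +
    qof * rowMeans(P[, K + seq_len(K), drop = FALSE])
  nd <- config$n_droplets
  w <- c(nd[["human_singlet"]] * mix(prm$profiles_human),
         nd[["mouse_singlet"]] * mix(prm$profiles_mouse))
  if (sum(w) == 0) return(0)
  w <- w / sum(w)
  sum(w * (prm$m_cross + prm$m_multi))
}

#' Write a simulated dataset to disk as plain-text artifacts
#'
#' Writes `combined/`, `human/` and `mouse/` 10x directories plus
#' `truth.tsv`, `ledger.tsv` and `composition.tsv`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @param gzip gzip the matrix files.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, gzip = FALSE) {
  stopifnot(inherits(sim, "xdeconv_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tenx(sim$combined, file.path(dir, "combined"), gzip = gzip)
  write_tenx(sim$human_view, file.path(dir, "human"), gzip = gzip)
  write_tenx(sim$mouse_view, file.path(dir, "mouse"), gzip = gzip)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  data.table::fwrite(sim$ledger, file.path(dir, "ledger.tsv"), sep = "\t")
  write.table(sim$composition, file.path(dir, "composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
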