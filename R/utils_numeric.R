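# Shared numerics: library-size normalization, variable genes, PCA
# embedding, kNN, and graph clustering. All seeded callers pass an explicit
# seed; nothing here touches the global RNG unless given one.

# counts-per-`scale` then log1p; genes x cells sparse in, sparse out
lognorm <- function(counts, scale = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = scale / cs)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

# indices of the n most variable rows of a (log-normalized) matrix
top_variable_genes <- function(x, n = 2000L) {
  mu <- Matrix::rowMeans(x)
  v <- Matrix::rowSums(x^2) / ncol(x) - mu^2
  head(order(v, decreasing = TRUE), min(n, nrow(x)))
}

# PCA embedding of cells: genes x cells in, cells x n_pcs out.
# Components are sign-fixed (largest-magnitude loading positive) so the
# embedding is deterministic given the seed.
pca_embed <- function(x, n_pcs = 20L, seed = 1L) {
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
  if (n_pcs < 1) stop_integrity("too few cells for a PCA embedding")
  set.seed(seed)
  xt <- Matrix::t(x)
  ctr <- Matrix::colMeans(xt)
  pc <- tryCatch(irlba::irlba(xt, nv = n_pcs, center = ctr),
                 error = function(e) NULL)
  if (is.null(pc)) {
    # degenerate input (e.g. constant matrix): fall back to exact PCA
    full <- prcomp(as.matrix(xt), center = TRUE, rank. = n_pcs)
    pc <- list(u = full$x[, seq_len(n_pcs), drop = FALSE] %*%
                 diag(1 / pmax(full$sdev[seq_len(n_pcs)], 1e-12), n_pcs),
               d = full$sdev[seq_len(n_pcs)],
               v = full$rotation[, seq_len(n_pcs), drop = FALSE])
  }
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- pc$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  emb <- sweep(pc$u %*% diag(pc$d, n_pcs), 2, flip, "*")
  rownames(emb) <- colnames(x)
  colnames(emb) <- paste0("PC", seq_len(n_pcs))
  emb
}

# k nearest neighbours (self excluded); returns n x k index matrix
knn_index <- function(emb, k) {
  k <- min(k, nrow(emb) - 1L)
  RANN::nn2(emb, emb, k = k + 1L)$nn.idx[, -1, drop = FALSE]
}

# community detection on a symmetrized kNN graph
knn_cluster <- function(emb, k = 20L, seed = 1L) {
  idx <- knn_index(emb, k)
  n <- nrow(emb)
  g <- igraph::graph_from_edgelist(
    cbind(rep(seq_len(n), ncol(idx)), as.vector(idx)), directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  igraph::membership(cl)
}

# scaled MAD with a floor so degenerate (constant) samples do not create
# zero-width acceptance bands
mad_floor <- function(x, eps = 1e-9) max(mad(x), eps)
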