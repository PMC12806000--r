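# Independent oracles and shared fixtures, built in code.

# O(n^2) concordance index: pairs with distinct labels, prediction ties
# score 0.5.
ci_brute_force <- function(y, p) {
  num <- 0
  den <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (y[i] == y[j]) next
      den <- den + 1
      hi <- if (y[i] > y[j]) i else j
      lo <- if (y[i] > y[j]) j else i
      if (p[hi] > p[lo]) num <- num + 1 else if (p[hi] == p[lo]) num <- num + 0.5
    }
  }
  num / den
}

# Dense graph-convolution oracle: sigma(D~^-1/2 (A+I) D~^-1/2 H W + b).
gcn_dense_oracle <- function(graph, H, W, b = 0, relu = TRUE) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges[, 1] + 1, graph$edges[, 2] + 1)] <- 1
  }
  At <- A + diag(n)
  Dm <- diag(1 / sqrt(rowSums(At)))
  Z <- sweep(Dm %*% At %*% Dm %*% H %*% W, 2, rep(b, length.out = ncol(W)), `+`)
  if (relu) pmax(Z, 0) else Z
}

# Random small molecular-graph-shaped object (valid undirected edge list,
# random features) for oracle tests that need arbitrary topologies.
random_graph <- function(n_max = 8, n_feat = 5) {
  n <- sample(2:n_max, 1)
  pairs <- t(utils::combn(n, 2)) - 1L
  keep <- stats::runif(nrow(pairs)) < 0.5
  # keep the graph simple but allow isolated nodes
  e <- pairs[keep, , drop = FALSE]
  edges <- rbind(e, e[, 2:1, drop = FALSE])
  structure(
    list(
      node_features = matrix(stats::rnorm(n * n_feat), n, n_feat),
      edges = edges, n_nodes = n, smiles = NA_character_
    ),
    class = "molecular_graph"
  )
}

# Small synthetic interaction set, featurized once per session.
.fixture_env <- new.env(parent = emptyenv())

tiny_featurized <- function(n = 24, L = 40, seed = 301, smiles_tokens = TRUE) {
  key <- paste("fz", n, L, seed, smiles_tokens, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    recs <- generate_dataset(synth_config(
      n_records = n, n_targets = 4, seed = seed,
      seq_len_range = c(20, 80), noise_sd = 0.3
    ))
    .fixture_env[[key]] <- featurize_dataset(
      recs, L = L,
      smiles_tokens = smiles_tokens, smiles_len = 30
    )
  }
  .fixture_env[[key]]
}

# A tiny spec that exercises every component but trains in seconds.
tiny_spec <- function(family = "bigraph", L = 40, ...) {
  args <- list(
    family = family,
    n_gcn_layers = 2L, gcn_widths = c(8L, 12L),
    fc_g1_dim = 10L, fc_g2_dim = 6L,
    embed_dim = 5L, bilstm_hidden = 4L,
    conv_filters = 4L, conv_kernel = 5L,
    fc1_xt_dim = 6L,
    head_dims = if (family == "deepdta") c(16L, 16L, 8L) else c(16L, 8L),
    dropout_rate = 0, seq_len = as.integer(L),
    smiles_len = 30L
  )
  do.call(model_spec, utils::modifyList(args, list(...)))
}

tiny_batch <- function(fz, idx = seq_len(min(8, length(fz$graphs)))) {
  fz <- bigraphdta:::.with_adjacency(fz)
  bigraphdta:::prepare_batch(fz, idx)
}
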