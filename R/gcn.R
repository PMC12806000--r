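# Graph-convolution mathematics: symmetric-normalized adjacency with
# self-loops, sparse layer propagation, and global max pooling.
#
# The propagation rule is the standard Kipf-Welling form
#   H^(l+1) = sigma( D~^(-1/2) (A + I) D~^(-1/2) H^(l) W^(l) )
# with d~_i = degree(i) + 1.

#' Symmetric-normalized adjacency with self-loops
#'
#' Computes the per-edge coefficients `1/sqrt(d~_i d~_j)` and per-node
#' self-loop coefficients `1/d~_i`, where `d~_i = degree(i) + 1`.
#'
#' @param graph A `molecular_graph` from [smiles_to_graph()] (any object
#'   with `n_nodes` and a 0-based directed `edges` matrix works).
#' @return Object of class `normalized_adjacency` with `n`, `edges`,
#'   `edge_coef` (aligned with the edge rows), and `self_coef` (length `n`).
#' @examples
#' adj <- normalize_adjacency(smiles_to_graph("CC"))
#' adj$self_coef # 0.5 0.5
#' @export
normalize_adjacency <- function(graph) {
  n <- graph$n_nodes
  edges <- graph$edges
  degree <- integer(n)
  if (nrow(edges) > 0) {
    tab <- table(factor(edges[, 1], levels = 0:(n - 1)))
    degree <- as.integer(tab)
  }
  d_tilde <- degree + 1
  edge_coef <- if (nrow(edges) > 0) {
    1 / sqrt(d_tilde[edges[, 1] + 1L] * d_tilde[edges[, 2] + 1L])
  } else {
    numeric(0)
  }
  structure(
    list(
      n = n, edges = edges, edge_coef = edge_coef,
      self_coef = 1 / d_tilde
    ),
    class = "normalized_adjacency"
  )
}

#' Sparse matrix form of a normalized adjacency
#'
#' @param adj A [normalize_adjacency()] result.
#' @return A symmetric sparse `dgCMatrix` of dimension `n x n`.
#' @export
adjacency_matrix <- function(adj) {
  Matrix::sparseMatrix(
    i = c(adj$edges[, 1] + 1L, seq_len(adj$n)),
    j = c(adj$edges[, 2] + 1L, seq_len(adj$n)),
    x = c(adj$edge_coef, adj$self_coef),
    dims = c(adj$n, adj$n)
  )
}

#' Specification of one graph-convolution layer
#'
#' @param in_dim,out_dim Layer dimensions.
#' @param W `in_dim x out_dim` weight matrix.
#' @param bias Length-`out_dim` bias vector (zeros reproduce the literal
#'   bias-free propagation rule).
#' @param activation `"relu"` or `"identity"`.
#' @return Object of class `gcn_layer_spec`.
#' @export
gcn_layer_spec <- function(in_dim, out_dim, W, bias = numeric(out_dim),
                           activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  W <- as.matrix(W)
  if (!all(dim(W) == c(in_dim, out_dim)) || !all(is.finite(W))) {
    stop_config("W must be a finite in_dim x out_dim matrix")
  }
  structure(
    list(
      in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
      W = W, bias = as.numeric(bias), activation = activation
    ),
    class = "gcn_layer_spec"
  )
}

#' One graph-convolution propagation step
#'
#' Computes `sigma(A_hat H W + bias)` where `A_hat` is the
#' symmetric-normalized self-loop adjacency, using the sparse edge-list
#' representation (cost linear in the number of edges).
#'
#' @param adj A [normalize_adjacency()] result.
#' @param H Node-feature matrix, `n x in_dim`.
#' @param layer A [gcn_layer_spec()].
#' @return `n x out_dim` matrix of propagated features.
#' @export
gcn_forward <- function(adj, H, layer) {
  H <- as.matrix(H)
  if (nrow(H) != adj$n) stop_invalid("H must have one row per graph node")
  if (ncol(H) != layer$in_dim) stop_invalid("H column count must equal in_dim")
  AH <- as.matrix(adjacency_matrix(adj) %*% H)
  Z <- sweep(AH %*% layer$W, 2, layer$bias, `+`)
  if (layer$activation == "relu") Z <- pmax(Z, 0)
  Z
}

#' Global max pooling over graph nodes
#'
#' @param H `n x F` node-feature matrix with `n >= 1`.
#' @return Length-`F` vector of column-wise maxima.
#' @export
global_max_pool <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) < 1) stop_invalid("cannot pool an empty node set")
  apply(H, 2, max)
}

#' Graph-convolution stack with pooled readout
#'
#' Applies a sequence of [gcn_forward()] layers to the graph's node
#' features and reads out a fixed-size graph vector by global max pooling.
#' The canonical stack has three ReLU layers with widths `(C, 2C, 4C)`.
#'
#' @param graph A `molecular_graph`.
#' @param layers List of [gcn_layer_spec()] with chaining dimensions;
#'   the first layer's `in_dim` must equal the node-feature width.
#' @param H0 Optional replacement for `graph$node_features`.
#' @return Pooled graph representation vector.
#' @export
gcn_stack <- function(graph, layers, H0 = graph$node_features) {
  H <- as.matrix(H0)
  if (ncol(H) != layers[[1]]$in_dim) {
    stop_config(sprintf(
      "first layer expects in_dim %d but node features have %d columns",
      layers[[1]]$in_dim, ncol(H)
    ))
  }
  adj <- normalize_adjacency(graph)
  for (k in seq_along(layers)) {
    if (k > 1 && layers[[k]]$in_dim != layers[[k - 1]]$out_dim) {
      stop_config(sprintf(
        "layer %d in_dim %d does not chain with layer %d out_dim %d",
        k, layers[[k]]$in_dim, k - 1, layers[[k - 1]]$out_dim
      ))
    }
    H <- gcn_forward(adj, H, layers[[k]])
  }
  global_max_pool(H)
}
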