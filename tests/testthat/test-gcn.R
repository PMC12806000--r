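# Graph-convolution core against a dense brute-force oracle.

test_that("normalized adjacency matches hand-computed coefficients", {
  # isolated node: self-coefficient 1
  lone <- structure(
    list(
      node_features = matrix(0, 1, 2),
      edges = matrix(integer(0), ncol = 2), n_nodes = 1L
    ),
    class = "molecular_graph"
  )
  expect_equal(normalize_adjacency(lone)$self_coef, 1)

  # two nodes, one bond: all four coefficients 0.5
  adj <- normalize_adjacency(smiles_to_graph("CC"))
  expect_equal(adj$self_coef, c(0.5, 0.5))
  expect_equal(adj$edge_coef, c(0.5, 0.5))

  # path 0-1-2: off-diagonal 1/sqrt(2*3), centre self-loop 1/3
  path <- structure(
    list(
      node_features = matrix(0, 3, 2),
      edges = cbind(c(0L, 1L, 1L, 2L), c(1L, 0L, 2L, 1L)), n_nodes = 3L
    ),
    class = "molecular_graph"
  )
  padj <- normalize_adjacency(path)
  expect_equal(padj$edge_coef, rep(1 / sqrt(6), 4))
  expect_equal(padj$self_coef[2], 1 / 3)
  # symmetry of the sparse form
  M <- as.matrix(adjacency_matrix(padj))
  expect_equal(M, t(M))
})

test_that("sparse propagation equals the dense normalized formula", {
  # identity case
  g1 <- structure(
    list(
      node_features = matrix(3.7, 1, 1),
      edges = matrix(integer(0), ncol = 2), n_nodes = 1L
    ),
    class = "molecular_graph"
  )
  layer <- gcn_layer_spec(1, 1, matrix(1), activation = "identity")
  expect_equal(
    gcn_forward(normalize_adjacency(g1), g1$node_features, layer),
    matrix(3.7)
  )

  # two-node averaging
  g2 <- smiles_to_graph("CC")
  H <- matrix(c(1, 3), 2, 1)
  expect_equal(
    gcn_forward(normalize_adjacency(g2), H, layer),
    matrix(c(2, 2), 2, 1)
  )

  # random graphs against the dense oracle
  withr::with_seed(13, {
    for (i in 1:50) {
      g <- random_graph()
      W <- matrix(stats::rnorm(5 * 3), 5, 3)
      b <- stats::rnorm(3)
      sp <- gcn_forward(
        normalize_adjacency(g), g$node_features,
        gcn_layer_spec(5, 3, W, b, "relu")
      )
      expect_equal(sp, gcn_dense_oracle(g, g$node_features, W, b, relu = TRUE),
        tolerance = 1e-5
      )
    }
  })
})

test_that("global max pooling takes column maxima and ignores node order", {
  expect_equal(global_max_pool(matrix(c(1, 3, 5, 2), 2, 2)), c(3, 5))
  expect_equal(global_max_pool(matrix(c(7, 8), 1, 2)), c(7, 8))
  H <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(global_max_pool(H), global_max_pool(H[sample(4), ]))
  expect_error(global_max_pool(matrix(0, 0, 2)), class = "dta_invalid_input")
})

test_that("the three-layer stack matches a dense recomputation on benzene", {
  g <- smiles_to_graph("c1ccccc1")
  C <- ncol(g$node_features)
  withr::with_seed(17, {
    dims <- c(C, 4L, 8L, 6L)
    layers <- lapply(1:3, function(l) {
      gcn_layer_spec(
        dims[l], dims[l + 1],
        matrix(stats::rnorm(dims[l] * dims[l + 1]), dims[l], dims[l + 1]),
        stats::rnorm(dims[l + 1]), "relu"
      )
    })
  })
  got <- gcn_stack(g, layers)
  H <- g$node_features
  for (ly in layers) H <- gcn_dense_oracle(g, H, ly$W, ly$bias, relu = TRUE)
  expect_equal(got, apply(H, 2, max), tolerance = 1e-5)

  # zero weights everywhere give the zero vector through relu
  zero_layers <- lapply(1:3, function(l) {
    gcn_layer_spec(dims[l], dims[l + 1], matrix(0, dims[l], dims[l + 1]))
  })
  expect_equal(gcn_stack(g, zero_layers), rep(0, 6))
})

test_that("the pooled stack output is invariant to node relabeling", {
  withr::with_seed(23, {
    for (i in 1:10) {
      g <- random_graph(n_max = 7, n_feat = 4)
      dims <- c(4L, 5L, 6L)
      layers <- lapply(1:2, function(l) {
        gcn_layer_spec(
          dims[l], dims[l + 1],
          matrix(stats::rnorm(dims[l] * dims[l + 1]), dims[l], dims[l + 1]),
          stats::rnorm(dims[l + 1]), "relu"
        )
      })
      perm <- sample(g$n_nodes)
      relabel <- (seq_len(g$n_nodes))[order(perm)] # new index of old node i
      g2 <- g
      g2$node_features <- g$node_features[perm, , drop = FALSE]
      g2$edges <- cbind(relabel[g$edges[, 1] + 1] - 1L, relabel[g$edges[, 2] + 1] - 1L)
      expect_equal(gcn_stack(g, layers), gcn_stack(g2, layers), tolerance = 1e-10)
    }
  })
})

test_that("propagation work scales with the edge count, not the node pairs", {
  # the sparse representation holds exactly one coefficient per directed
  # edge plus one per node, so per-layer work is O(|E| + N)
  for (n in c(4, 8, 16)) {
    edges <- cbind(0:(n - 2), 1:(n - 1))
    path <- structure(
      list(
        node_features = matrix(0, n, 2),
        edges = rbind(edges, edges[, 2:1]), n_nodes = as.integer(n)
      ),
      class = "molecular_graph"
    )
    adj <- normalize_adjacency(path)
    nnz <- length(adj$edge_coef) + length(adj$self_coef)
    expect_equal(nnz, nrow(path$edges) + n)
  }
})

test_that("dimension mismatches raise configuration errors", {
  g <- smiles_to_graph("CCO")
  bad <- gcn_layer_spec(4, 3, matrix(0, 4, 3))
  expect_error(
    gcn_forward(normalize_adjacency(g), g$node_features, bad),
    class = "dta_invalid_input"
  )
  l1 <- gcn_layer_spec(78, 5, matrix(0, 78, 5))
  l2 <- gcn_layer_spec(6, 2, matrix(0, 6, 2))
  expect_error(gcn_stack(g, list(l1, l2)), class = "dta_config_error")
})
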