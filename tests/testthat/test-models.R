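# Model construction, registry, forward contracts, checkpoints.

test_that("parameter initialization is deterministic and registry complete", {
  spec <- tiny_spec("bigraph")
  m1 <- build_model(spec, seed = 5)
  m2 <- build_model(spec, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, seed = 6)
  expect_false(identical(m1$params, m3$params))

  expect_equal(
    names(layer_registry(m1)),
    c(
      "gcn1", "gcn2", "fc_g1", "fc_g2", "embed_xt", "protein_core",
      "fc1_xt", "fc1", "fc2", "out"
    )
  )
  # default three-layer spec gains gcn3; two-layer spec lacks it
  full <- build_model(model_spec_small("bigraph"), seed = 1)
  expect_true("gcn3" %in% names(full$registry))
  expect_false("gcn3" %in% names(m1$registry))

  # every parameter belongs to exactly one group
  all_names <- unlist(m1$registry, use.names = FALSE)
  expect_setequal(all_names, names(m1$params))
  expect_equal(anyDuplicated(all_names), 0)
})

test_that("evaluation forwards are deterministic; dropout only acts in training", {
  fz <- tiny_featurized()
  batch <- tiny_batch(fz)
  model <- build_model(tiny_spec("bigraph", dropout_rate = 0.4), seed = 2)
  e1 <- bigraphdta:::forward_batch(model, batch, training = FALSE)$yhat
  e2 <- bigraphdta:::forward_batch(model, batch, training = FALSE)$yhat
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  withr::with_seed(10, {
    t1 <- bigraphdta:::forward_batch(model, batch, training = TRUE)$yhat
    t2 <- bigraphdta:::forward_batch(model, batch, training = TRUE)$yhat
  })
  expect_false(identical(t1, t2))
})

test_that("batched forwards equal per-record forwards for all families", {
  fz <- tiny_featurized()
  for (family in c("bigraph", "graphdta_gcn", "deepdta")) {
    spec <- tiny_spec(family,
      smiles_vocab_size = if (family == "deepdta") fz$smiles_vocab$size else NULL
    )
    model <- build_model(spec, seed = 3)
    idx <- 1:10
    batched <- predict_affinity(model, fz, idx, batch_size = 10)
    single <- vapply(
      idx,
      function(i) predict_affinity(model, fz, i, batch_size = 1),
      numeric(1)
    )
    expect_equal(batched, single, tolerance = 1e-5)
  }
})

test_that("the protein branch carries signal", {
  fz <- tiny_featurized()
  model <- build_model(tiny_spec("bigraph"), seed = 4)
  # same drug, two different sequences -> different predictions
  fz2 <- fz
  fz2$tokens[1, ] <- fz$tokens[2, ]
  p1 <- predict_affinity(model, fz, 1)
  p2 <- predict_affinity(model, fz2, 1)
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("last-hidden mode ignores trailing padding beyond the sequence", {
  seqs <- tibble::tibble(
    smiles = c("CCO", "CCN"),
    target_id = "T1",
    sequence = c("MKVLAWYHE", "ACDEFGHIK"),
    pic50 = c(5, 6)
  )
  fz30 <- featurize_dataset(seqs, L = 30)
  fz50 <- featurize_dataset(seqs, L = 50)
  spec30 <- tiny_spec("bigraph", L = 30, bilstm_mode = "last_hidden")
  spec50 <- tiny_spec("bigraph", L = 50, bilstm_mode = "last_hidden")
  m30 <- build_model(spec30, seed = 8)
  m50 <- build_model(spec50, seed = 8)
  # identical parameters (no shape depends on L in this mode)
  expect_identical(m30$params, m50$params)
  expect_equal(
    predict_affinity(m30, fz30),
    predict_affinity(m50, fz50),
    tolerance = 1e-10
  )
})

test_that("convolutional token model scales conv1 parameters linearly in f", {
  fz <- tiny_featurized()
  s1 <- tiny_spec("deepdta", conv_filters = 4L, smiles_vocab_size = fz$smiles_vocab$size)
  s2 <- tiny_spec("deepdta", conv_filters = 8L, smiles_vocab_size = fz$smiles_vocab$size)
  m1 <- build_model(s1, seed = 1)
  m2 <- build_model(s2, seed = 1)
  expect_equal(
    length(m2$params[["drug_core.conv1.W"]]),
    2 * length(m1$params[["drug_core.conv1.W"]])
  )
  # different protein core from the graph families
  mg <- build_model(tiny_spec("graphdta_gcn"), seed = 1)
  mb <- build_model(tiny_spec("bigraph"), seed = 1)
  expect_false(identical(
    names(mg$params[startsWith(names(mg$params), "protein_core")]),
    names(mb$params[startsWith(names(mb$params), "protein_core")])
  ))
})

test_that("extracted fused features have branch widths and respond to training", {
  fz <- tiny_featurized()
  spec <- tiny_spec("bigraph")
  model <- build_model(spec, seed = 6)
  feats <- extract_drug_protein_features(model, fz, 1:8)
  expect_equal(dim(feats), c(8, spec$fc_g2_dim + spec$fc1_xt_dim))
  expect_identical(feats, extract_drug_protein_features(model, fz, 1:8))

  split <- list(train_indices = 1:16, test_indices = 17:24)
  fit <- train(model, fz, split,
    train_config(epochs = 3, batch_size = 8, seed = 1),
    val_fraction = 0
  )
  feats2 <- extract_drug_protein_features(fit$model, fz, 1:8)
  expect_false(identical(feats, feats2))
})

test_that("checkpoints restore bit-identical evaluation forwards", {
  fz <- tiny_featurized()
  model <- build_model(tiny_spec("bigraph"), seed = 7,
    meta = list(L = fz$L, vocab = fz$vocab)
  )
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  expect_identical(
    predict_affinity(model, fz, 1:6),
    predict_affinity(restored, fz, 1:6)
  )
  expect_equal(restored$meta$L, fz$L)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), other)
  expect_error(load_checkpoint(other), class = "dta_config_error")
})

test_that("inconsistent specs are rejected at construction", {
  expect_error(model_spec(n_gcn_layers = 5L), class = "dta_config_error")
  expect_error(model_spec(dropout_rate = 1), class = "dta_config_error")
  expect_error(model_spec(gcn_widths = c(8L, 8L)), class = "dta_config_error")
  expect_error(
    build_model(model_spec("deepdta"), seed = 1),
    class = "dta_config_error"
  ) # missing SMILES vocabulary size
})
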