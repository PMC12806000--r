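# Penalties, freezing, the training loop, transfer, cross-validation.

fz <- tiny_featurized()
tiny_split <- list(train_indices = 1:16, test_indices = 17:24)
fast_cfg <- function(epochs = 2, seed = 1, optimizer = "rmsprop",
                     learning_rate = 5e-4) {
  train_config(
    learning_rate = learning_rate, batch_size = 8L,
    optimizer = optimizer, epochs = epochs, seed = seed
  )
}

test_that("penalties match hand computation on known weights", {
  model <- build_model(tiny_spec("bigraph"), seed = 1)
  # zero everything in the head groups, then plant two known weights
  for (nm in unlist(model$registry[c("fc1", "fc2")])) {
    model$params[[nm]][] <- 0
  }
  model$params[["fc1.W"]][1] <- 1
  model$params[["fc1.W"]][2] <- -2
  expect_equal(
    penalty(model, regularization_spec("l1", lambda1 = 1e-5, selector = "head_fc")),
    3e-5
  )
  expect_equal(
    penalty(model, regularization_spec("l2", lambda2 = 1e-5, selector = "head_fc")),
    5e-5
  )
  expect_equal(
    penalty(model, regularization_spec("elasticnet",
      lambda1 = 1e-5, lambda2 = 1e-5, selector = "head_fc"
    )),
    8e-5
  )
  expect_equal(penalty(model, regularization_spec("none")), 0)
  expect_error(
    penalty(model, regularization_spec("l1", selector = c("fc1", "nope"))),
    class = "dta_config_error"
  )
})

test_that("penalty gradients agree with finite differences away from zero", {
  model <- build_model(tiny_spec("bigraph"), seed = 2)
  for (kind in c("l1", "l2", "elasticnet")) {
    reg <- regularization_spec(kind, lambda1 = 1e-3, lambda2 = 1e-3, selector = "branch_fc")
    w <- model$params[["fc_g2.W"]]
    idx <- which(abs(w) > 1e-3)[1:5]
    g <- bigraphdta:::.penalty_grad(w, reg)
    for (ix in idx) {
      eps <- 1e-6
      m_p <- model
      m_p$params[["fc_g2.W"]][ix] <- w[ix] + eps
      m_m <- model
      m_m$params[["fc_g2.W"]][ix] <- w[ix] - eps
      num <- (penalty(m_p, reg) - penalty(m_m, reg)) / (2 * eps)
      expect_equal(g[ix], num, tolerance = 1e-4)
    }
  }
})

test_that("reported train loss decomposes into mse plus penalty", {
  reg <- regularization_spec("elasticnet", 1e-3, 1e-3, selector = "all")
  model <- build_model(tiny_spec("bigraph"), seed = 3) # dropout 0
  single <- list(train_indices = 1:8, test_indices = 17:24)
  fit <- train(model, fz, single, fast_cfg(epochs = 1, optimizer = "sgd"),
    reg = reg, val_fraction = 0
  )
  # one batch, loss measured before the (only) update: recompute at init
  p0 <- predict_affinity(model, fz, 1:8)
  expected <- mean((p0 - fz$labels[1:8])^2) + penalty(model, reg)
  expect_equal(fit$report$log$train_loss[1], expected, tolerance = 1e-6)
})

test_that("an extreme l1 penalty dominates the first-epoch loss", {
  model <- build_model(tiny_spec("bigraph"), seed = 4)
  plain <- train(model, fz, tiny_split, fast_cfg(epochs = 1), val_fraction = 0)
  heavy <- train(model, fz, tiny_split, fast_cfg(epochs = 1),
    reg = regularization_spec("l1", lambda1 = 1),
    val_fraction = 0
  )
  expect_gt(heavy$report$log$train_loss[1], plain$report$log$train_loss[1])
})

test_that("freeze policies change exactly the allowed parameter groups", {
  cases <- list(
    list(policy = freeze_policy("freeze_all_but_out"), groups = "out"),
    list(policy = freeze_policy("head_only"), groups = c("fc1", "fc2", "out")),
    list(policy = freeze_policy("mixed"), groups = c("fc_g2", "fc1_xt", "fc2", "out")),
    list(
      policy = freeze_policy("custom", trainable = c("gcn1", "fc1")),
      groups = c("gcn1", "fc1", "out")
    )
  )
  for (case in cases) {
    model <- build_model(tiny_spec("bigraph"), seed = 5)
    fit <- train(model, fz, tiny_split, fast_cfg(epochs = 5),
      policy = case$policy, val_fraction = 0
    )
    changed <- names(model$params)[vapply(
      names(model$params),
      function(nm) !identical(model$params[[nm]], fit$model$params[[nm]]),
      logical(1)
    )]
    changed_groups <- unique(sub("\\..*$", "", changed))
    expect_setequal(changed_groups, case$groups)
    # frozen parameters are bitwise unchanged
    frozen <- setdiff(names(model$params), unlist(model$registry[case$groups]))
    for (nm in frozen) {
      expect_identical(model$params[[nm]], fit$model$params[[nm]])
    }
  }
})

test_that("unfreezing everything updates every layer", {
  model <- build_model(tiny_spec("bigraph"), seed = 6)
  fit <- train(model, fz, tiny_split, fast_cfg(epochs = 2), val_fraction = 0)
  for (nm in names(model$params)) {
    expect_false(identical(model$params[[nm]], fit$model$params[[nm]]))
  }
  expect_error(freeze_policy("custom"), class = "dta_config_error")
})

test_that("identical seed and config reproduce the run exactly", {
  for (opt in c("rmsprop", "adam", "sgd")) {
    m1 <- build_model(tiny_spec("bigraph", dropout_rate = 0.2), seed = 7)
    m2 <- build_model(tiny_spec("bigraph", dropout_rate = 0.2), seed = 7)
    expect_identical(m1$params, m2$params)
    f1 <- train(m1, fz, tiny_split, fast_cfg(epochs = 2, optimizer = opt))
    f2 <- train(m2, fz, tiny_split, fast_cfg(epochs = 2, optimizer = opt))
    expect_identical(f1$report$log$train_loss[1], f2$report$log$train_loss[1])
    expect_identical(f1$report$log, f2$report$log)
  }
})

test_that("non-finite losses abort with a diagnostic", {
  model <- build_model(tiny_spec("bigraph"), seed = 8)
  err <- expect_error(
    train(model, fz, tiny_split,
      fast_cfg(epochs = 30, learning_rate = 1e4, optimizer = "sgd"),
      val_fraction = 0
    ),
    class = "dta_invalid_input"
  )
  expect_match(conditionMessage(err), "epoch")
})

test_that("transfer warm-starts, respects freezing and can add head layers", {
  base <- build_model(tiny_spec("bigraph"), seed = 9)
  pre <- train(base, fz, tiny_split, fast_cfg(epochs = 2), val_fraction = 0)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(pre$best_model, path)

  # warm-start identity: before any step the loaded model predicts like
  # the pretrained one
  loaded <- load_checkpoint(path)
  expect_identical(
    predict_affinity(loaded, fz, tiny_split$test_indices),
    predict_affinity(pre$best_model, fz, tiny_split$test_indices)
  )

  frozen <- transfer(path, fz, tiny_split, fast_cfg(epochs = 2),
    policy = freeze_policy("freeze_all_but_out"), val_fraction = 0
  )
  for (nm in setdiff(names(loaded$params), loaded$registry$out)) {
    expect_identical(frozen$model$params[[nm]], loaded$params[[nm]])
  }

  extended <- transfer(path, fz, tiny_split, fast_cfg(epochs = 1),
    extra_layers = 2L, val_fraction = 0
  )
  expect_true(all(c("extra_head_1", "extra_head_2") %in%
    names(extended$model$registry)))

  # featurization mismatch is named
  fz_short <- tiny_featurized(L = 20, seed = 302)
  err <- expect_error(
    transfer(path, fz_short, tiny_split, fast_cfg(epochs = 1)),
    class = "dta_config_error"
  )
  expect_match(conditionMessage(err), "seq_len")
})

test_that("cross-validation partitions folds and summarizes metrics", {
  factory <- function(seed) build_model(tiny_spec("bigraph"), seed = seed)
  cv <- run_cv(factory, fz, 1:18, k = 3, cfg = fast_cfg(epochs = 2))
  expect_length(cv$reports, 3)
  held <- sort(unlist(lapply(cv$reports, function(ft) ft$split$test_indices)))
  expect_equal(held, 1:18)
  best_mses <- vapply(
    cv$reports,
    function(ft) ft$report$metrics_at_best$test_mse, numeric(1)
  )
  expect_gte(cv$summary$mean[cv$summary$metric == "mse"], min(best_mses))
  expect_lte(cv$summary$mean[cv$summary$metric == "mse"], max(best_mses))
})

test_that("run reports are recomputable from their serialized log", {
  model <- build_model(tiny_spec("bigraph"), seed = 10)
  fit <- train(model, fz, tiny_split, fast_cfg(epochs = 4), val_fraction = 0.2)
  report <- fit$report
  expect_equal(
    report$best_epoch,
    report$log$epoch[which.min(report$log$test_mse)]
  )
  dir <- withr::local_tempdir()
  write_run_report(report, dir)
  log2 <- read_epoch_log(file.path(dir, "log.jsonl"))
  expect_equal(nrow(log2), 4)
  rebuilt <- run_report(log2)
  expect_equal(rebuilt$best_epoch, report$best_epoch)
  expect_equal(rebuilt$metrics_at_best$test_mse, report$metrics_at_best$test_mse)
  expect_equal(rebuilt$per_metric_bests$best, report$per_metric_bests$best)
})
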