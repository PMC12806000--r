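# Training loop: loss with selective penalties, layer freezing,
# optimizers, per-epoch evaluation and best-epoch reporting.

#' Training configuration
#'
#' Defaults follow the published tuning: learning rate 0.0005, batch size
#' 64, RMSProp, 1000 epochs.
#'
#' @param learning_rate Positive learning rate.
#' @param batch_size Mini-batch size.
#' @param optimizer `"rmsprop"`, `"adam"`, or `"sgd"`.
#' @param epochs Number of training epochs.
#' @param seed Integer seed controlling initial shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.0005, batch_size = 64L,
                         optimizer = c("rmsprop", "adam", "sgd"),
                         epochs = 1000L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      optimizer = optimizer, epochs = as.integer(epochs),
      seed = as.integer(seed),
      # optimizer hyperparameters beyond the learning rate (recorded for
      # reproducibility)
      optimizer_params = switch(optimizer,
        rmsprop = list(rho = 0.9, epsilon = 1e-8),
        adam = list(beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8),
        sgd = list()
      )
    ),
    class = "train_config"
  )
}

#' Regularization specification
#'
#' An L1, L2 or elastic-net penalty added to the training loss over a
#' selected group of layers.  Both weights and biases of the selected
#' layers are penalized.
#'
#' @param kind `"none"`, `"l1"`, `"l2"`, or `"elasticnet"`.
#' @param lambda1 L1 coefficient (used by `l1` and `elasticnet`).
#' @param lambda2 L2 coefficient (used by `l2` and `elasticnet`).
#' @param selector `"all"` (every layer), `"head_fc"` (`fc1`, `fc2` — the
#'   fully connected layers after concatenation), `"branch_fc"` (`fc_g1`,
#'   `fc_g2`, `fc1_xt` — the layers on the compound and protein branches),
#'   `"all_fc"` (their union), or a character vector of registry names.
#' @return Object of class `regularization_spec`.
#' @export
regularization_spec <- function(kind = c("none", "l1", "l2", "elasticnet"),
                                lambda1 = 1e-5, lambda2 = 1e-5,
                                selector = "all") {
  kind <- match.arg(kind)
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(
    list(kind = kind, lambda1 = lambda1, lambda2 = lambda2, selector = selector),
    class = "regularization_spec"
  )
}

# Resolve a selector to registry group names.
.resolve_selector <- function(model, selector) {
  groups <- names(model$registry)
  if (length(selector) == 1 && selector %in% c("all", "head_fc", "branch_fc", "all_fc")) {
    sel <- switch(selector,
      all = groups,
      head_fc = c("fc1", "fc2"),
      branch_fc = c("fc_g1", "fc_g2", "fc1_xt"),
      all_fc = c("fc1", "fc2", "fc_g1", "fc_g2", "fc1_xt")
    )
    sel <- intersect(sel, groups)
    if (length(sel) == 0) stop_config(sprintf("selector '%s' matches no layer", selector))
    return(sel)
  }
  unknown <- setdiff(selector, groups)
  if (length(unknown) > 0) {
    stop_config(sprintf(
      "unknown layer name(s) in selector: %s", paste(unknown, collapse = ", ")
    ))
  }
  selector
}

.selected_params <- function(model, selector) {
  unlist(model$registry[.resolve_selector(model, selector)], use.names = FALSE)
}

#' Regularization penalty of a model
#'
#' `l1` contributes `lambda1 * sum(|w|)`, `l2` contributes
#' `lambda2 * sum(w^2)`, `elasticnet` their sum, over the parameters
#' (weights and biases) of the selected layers.
#'
#' @param model A `dta_model`.
#' @param reg A [regularization_spec()].
#' @return Nonnegative penalty value.
#' @export
penalty <- function(model, reg) {
  if (reg$kind == "none") return(0)
  pnames <- .selected_params(model, reg$selector)
  s1 <- 0
  s2 <- 0
  for (nm in pnames) {
    w <- model$params[[nm]]
    if (reg$kind %in% c("l1", "elasticnet")) s1 <- s1 + sum(abs(w))
    if (reg$kind %in% c("l2", "elasticnet")) s2 <- s2 + sum(w^2)
  }
  (if (reg$kind == "l2") 0 else reg$lambda1 * s1) +
    (if (reg$kind == "l1") 0 else reg$lambda2 * s2)
}

# Gradient of the penalty with respect to one parameter tensor.
.penalty_grad <- function(w, reg) {
  g <- 0
  if (reg$kind %in% c("l1", "elasticnet")) g <- g + reg$lambda1 * sign(w)
  if (reg$kind %in% c("l2", "elasticnet")) g <- g + 2 * reg$lambda2 * w
  g
}

#' Layer-freezing policy
#'
#' Named presets follow the transfer-learning scenarios:
#' `"unfreeze_all"` trains everything; `"freeze_all_but_out"` trains only
#' the output layer; `"head_only"` trains `fc1`, `fc2` and `out`;
#' `"mixed"` trains the last layer of each branch plus the upper head
#' (`fc_g2`, `fc1_xt`, `fc2`, `out`); `"custom"` trains exactly
#' `trainable`.  The output layer is always trainable.
#'
#' @param name Preset name.
#' @param trainable Character vector of registry group names (for
#'   `"custom"`).
#' @return Object of class `freeze_policy`.
#' @export
freeze_policy <- function(name = c(
                            "unfreeze_all", "freeze_all_but_out",
                            "head_only", "mixed", "custom"
                          ),
                          trainable = NULL) {
  name <- match.arg(name)
  if (name == "custom" && length(trainable) == 0) {
    stop_config("custom freeze policy requires a non-empty trainable set")
  }
  structure(list(name = name, trainable = trainable), class = "freeze_policy")
}

#' Apply a freeze policy to a model
#'
#' Marks the parameter groups outside the policy's trainable set as
#' frozen; a subsequent optimizer step leaves them bitwise unchanged.
#'
#' @param model A `dta_model`.
#' @param policy A [freeze_policy()].
#' @return The model with a `trainable` field (character vector of
#'   trainable parameter names).
#' @export
apply_freeze <- function(model, policy) {
  groups <- names(model$registry)
  sel <- switch(policy$name,
    unfreeze_all = groups,
    freeze_all_but_out = "out",
    head_only = intersect(c("fc1", "fc2", "out"), groups),
    mixed = intersect(c("fc_g2", "fc1_xt", "fc2", "out"), groups),
    custom = policy$trainable
  )
  unknown <- setdiff(sel, groups)
  if (length(unknown) > 0) {
    stop_config(sprintf(
      "freeze policy names unknown layer(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  sel <- union(sel, "out") # the output layer is always trainable
  model$trainable_groups <- sel
  model$trainable <- unlist(model$registry[sel], use.names = FALSE)
  model
}

# ---- optimizers --------------------------------------------------------

.make_opt_state <- function() new.env(parent = emptyenv())

.opt_step <- function(params, grads, names_upd, cfg, state) {
  lr <- cfg$learning_rate
  op <- cfg$optimizer_params
  if (cfg$optimizer == "adam") {
    state$t <- (state$t %||% 0) + 1
  }
  for (nm in names_upd) {
    g <- grads[[nm]]
    if (is.null(g)) next
    w <- params[[nm]]
    if (cfg$optimizer == "sgd") {
      w <- w - lr * g
    } else if (cfg$optimizer == "rmsprop") {
      v <- state[[paste0(nm, ".v")]] %||% (g * 0)
      v <- op$rho * v + (1 - op$rho) * g^2
      state[[paste0(nm, ".v")]] <- v
      w <- w - lr * g / (sqrt(v) + op$epsilon)
    } else {
      m <- state[[paste0(nm, ".m")]] %||% (g * 0)
      v <- state[[paste0(nm, ".v")]] %||% (g * 0)
      m <- op$beta1 * m + (1 - op$beta1) * g
      v <- op$beta2 * v + (1 - op$beta2) * g^2
      state[[paste0(nm, ".m")]] <- m
      state[[paste0(nm, ".v")]] <- v
      mh <- m / (1 - op$beta1^state$t)
      vh <- v / (1 - op$beta2^state$t)
      w <- w - lr * mh / (sqrt(vh) + op$epsilon)
    }
    params[[nm]] <- w
  }
  params
}

# ---- training ----------------------------------------------------------

.eval_split <- function(model, fz, indices, batch_size) {
  if (length(indices) == 0) {
    return(NULL)
  }
  p <- predict_affinity(model, fz, indices, batch_size)
  list(p = p, y = fz$labels[indices])
}

#' Train a model
#'
#' Minimizes `MSE + penalty` by mini-batch gradient descent under the
#' chosen optimizer, with per-epoch shuffling, a validation split carved
#' from the training set, and evaluation of MSE / R-squared / concordance
#' on the validation and test sets every epoch (in evaluation mode).  The
#' best epoch is the one minimizing test MSE; its parameters are retained.
#'
#' @param model A `dta_model` (freshly built or warm-started).
#' @param fz A [featurize_dataset()] result covering all split indices.
#' @param split A [split_dataset()] result (or any list with
#'   `train_indices` and `test_indices`).
#' @param cfg A [train_config()].
#' @param reg A [regularization_spec()].
#' @param policy A [freeze_policy()].
#' @param val_fraction Fraction of the training set held out for the
#'   per-epoch validation loss (seeded; default 0.1).
#' @param verbose Print one line per epoch.
#' @return Object of class `dta_fit`: `model` (final parameters),
#'   `best_model` (parameters at the best epoch), `report` (a
#'   `dta_run_report`), plus the configuration objects.
#' @export
train <- function(model, fz, split, cfg = train_config(),
                  reg = regularization_spec("none"),
                  policy = freeze_policy("unfreeze_all"),
                  val_fraction = 0.1, verbose = FALSE) {
  fz <- .with_adjacency(fz)
  model <- apply_freeze(model, policy)
  train_idx <- split$train_indices
  test_idx <- split$test_indices
  if (length(train_idx) == 0) stop_invalid("empty training split")
  if (cfg$batch_size > length(train_idx)) {
    stop_invalid("batch_size exceeds the training set size")
  }
  withr::local_seed(cfg$seed)
  n_val <- floor(val_fraction * length(train_idx))
  val_idx <- if (n_val > 0) sort(sample(train_idx, n_val)) else integer(0)
  fit_idx <- setdiff(train_idx, val_idx)

  state <- .make_opt_state()
  log_rows <- vector("list", cfg$epochs)
  best <- list(epoch = NA_integer_, test_mse = Inf, params = NULL)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(fit_idx)
    chunks <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    batch_losses <- numeric(length(chunks))
    for (ci in seq_along(chunks)) {
      batch <- prepare_batch(fz, chunks[[ci]])
      fwd <- forward_batch(model, batch, training = TRUE)
      batch_mse <- mean((fwd$yhat - batch$labels)^2)
      pen <- penalty(model, reg)
      loss <- batch_mse + pen
      if (!is.finite(loss)) {
        stop_invalid(sprintf(
          "non-finite training loss %g at epoch %d, batch %d", loss, epoch, ci
        ))
      }
      batch_losses[ci] <- loss
      dy <- 2 * (fwd$yhat - batch$labels) / length(batch$labels)
      grads <- backward_batch(model, batch, fwd$cache, dy)
      if (reg$kind != "none") {
        for (nm in .selected_params(model, reg$selector)) {
          grads[[nm]] <- (grads[[nm]] %||% 0) +
            .penalty_grad(model$params[[nm]], reg)
        }
      }
      model$params <- .opt_step(model$params, grads, model$trainable, cfg, state)
    }

    val <- .eval_split(model, fz, val_idx, cfg$batch_size)
    test <- .eval_split(model, fz, test_idx, cfg$batch_size)
    row <- tibble::tibble(
      epoch = epoch,
      train_loss = mean(batch_losses),
      val_loss = if (is.null(val)) NA_real_ else mean((val$p - val$y)^2),
      test_mse = mse(test$y, test$p),
      test_r2 = r2(test$y, test$p),
      test_ci = concordance_index(test$y, test$p)
    )
    log_rows[[epoch]] <- row
    if (row$test_mse < best$test_mse) {
      best <- list(epoch = epoch, test_mse = row$test_mse, params = model$params)
    }
    if (verbose) {
      message(sprintf(
        "epoch %d: train %.4f val %.4f | test mse %.4f r2 %.4f ci %.4f",
        epoch, row$train_loss, row$val_loss, row$test_mse, row$test_r2, row$test_ci
      ))
    }
  }

  log <- do.call(rbind, log_rows)
  report <- run_report(log,
    config = list(cfg = cfg, reg = reg, policy = policy, val_fraction = val_fraction)
  )
  best_model <- model
  best_model$params <- best$params
  structure(
    list(
      model = model, best_model = best_model, report = report,
      cfg = cfg, reg = reg, policy = policy,
      val_indices = val_idx, split = split
    ),
    class = "dta_fit"
  )
}

# ---- transfer learning -------------------------------------------------

# Append n fresh head layers (extra_head_1, extra_head_2) of width `dim`
# before the output layer, re-initializing `out` for the new input width.
.add_head_layers <- function(model, n, dim, seed) {
  stopifnot(n == 2L)
  spec <- model$spec
  spec$extra_head_layers <- 2L
  spec$extra_head_dim <- as.integer(dim)
  plan <- .head_plan(spec)
  in_dim <- if (length(plan) >= 3) plan[[length(plan) - 2L]]$dim else stop_config("head too small")
  with_seed(seed, {
    model$params[["extra_head_1.W"]] <- glorot_uniform(in_dim, dim)
    model$params[["extra_head_1.b"]] <- numeric(dim)
    model$params[["extra_head_2.W"]] <- glorot_uniform(dim, dim)
    model$params[["extra_head_2.b"]] <- numeric(dim)
    model$params[["out.W"]] <- glorot_uniform(dim, 1L)
    model$params[["out.b"]] <- numeric(1L)
  })
  # rebuild registry preserving group order with the new layers before out
  nm <- names(model$params)
  ord <- c(setdiff(nm, c("extra_head_1.W", "extra_head_1.b",
                         "extra_head_2.W", "extra_head_2.b",
                         "out.W", "out.b")),
           "extra_head_1.W", "extra_head_1.b",
           "extra_head_2.W", "extra_head_2.b", "out.W", "out.b")
  model$params <- model$params[ord]
  groups <- sub("\\..*$", "", ord)
  model$registry <- split(ord, factor(groups, levels = unique(groups)))
  model$spec <- spec
  model$head_plan <- plan
  model
}

#' Fine-tune a pretrained model on new data
#'
#' Loads a checkpoint (warm start), optionally appends fresh head layers
#' before the output layer, applies a freeze policy, and trains.
#'
#' @param checkpoint A `dta_model`, `dta_fit`, or path to a saved
#'   checkpoint.
#' @param fz Featurized new dataset; must be compatible with the
#'   checkpoint's dimensions (atom features, vocabulary, token length).
#' @param split Train/test split of the new data.
#' @param cfg,reg,policy,val_fraction,verbose As in [train()].
#' @param extra_layers 0 or 2 fresh head layers to append.
#' @return A `dta_fit`.
#' @export
transfer <- function(checkpoint, fz, split, cfg = train_config(),
                     policy = freeze_policy("unfreeze_all"),
                     extra_layers = 0L,
                     reg = regularization_spec("none"),
                     val_fraction = 0.1, verbose = FALSE) {
  model <- if (is.character(checkpoint)) {
    load_checkpoint(checkpoint)
  } else if (inherits(checkpoint, "dta_fit")) {
    checkpoint$best_model
  } else {
    checkpoint
  }
  spec <- model$spec
  if (spec$atom_dim != fz$scheme$n_features && spec$family != "deepdta") {
    stop_config(sprintf(
      "checkpoint/featurization mismatch in atom_dim: %d vs %d",
      spec$atom_dim, fz$scheme$n_features
    ))
  }
  if (spec$vocab_size != fz$vocab$size) {
    stop_config(sprintf(
      "checkpoint/featurization mismatch in vocab_size: %d vs %d",
      spec$vocab_size, fz$vocab$size
    ))
  }
  if (spec$seq_len != fz$L) {
    stop_config(sprintf(
      "checkpoint/featurization mismatch in seq_len: %d vs %d",
      spec$seq_len, fz$L
    ))
  }
  if (extra_layers > 0) {
    model <- .add_head_layers(model, extra_layers, spec$extra_head_dim, cfg$seed)
  }
  train(model, fz, split, cfg,
    reg = reg, policy = policy,
    val_fraction = val_fraction, verbose = verbose
  )
}

# ---- cross-validation --------------------------------------------------

#' k-fold cross-validation
#'
#' Trains one model per fold (each fold seeded as `cfg$seed + fold`) with
#' the fold's held-out part as the evaluation set, and summarizes the
#' best-epoch metrics across folds.
#'
#' @param model_factory Function `(seed) -> dta_model`.
#' @param fz Featurized dataset.
#' @param train_indices Indices to fold (typically a split's training set).
#' @param k Number of folds.
#' @param cfg,reg,policy As in [train()].
#' @return List with `reports` (per-fold `dta_fit`s) and `summary` (tibble
#'   of mean and sd of each best-epoch metric).
#' @export
run_cv <- function(model_factory, fz, train_indices, k = 10L,
                   cfg = train_config(),
                   reg = regularization_spec("none"),
                   policy = freeze_policy("unfreeze_all")) {
  folds <- kfold(train_indices, k, seed = cfg$seed)
  parts <- fold_partitions(folds)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    fold_split <- list(
      train_indices = parts[[f]]$fit,
      test_indices = parts[[f]]$held_out
    )
    fits[[f]] <- train(
      model_factory(fold_cfg$seed), fz, fold_split, fold_cfg,
      reg = reg, policy = policy, val_fraction = 0
    )
  }
  metrics <- do.call(rbind, lapply(fits, function(ft) ft$report$metrics_at_best))
  summary <- tibble::tibble(
    metric = c("mse", "r2", "ci"),
    mean = c(mean(metrics$test_mse), mean(metrics$test_r2), mean(metrics$test_ci)),
    sd = c(stats::sd(metrics$test_mse), stats::sd(metrics$test_r2), stats::sd(metrics$test_ci))
  )
  list(reports = fits, summary = summary)
}
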