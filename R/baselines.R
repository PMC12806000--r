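# Classical-regressor baselines behind a uniform contract: support vector
# regression, random forests and gradient boosting, on either learned
# drug/protein features or raw token vectors.

#' Baseline regressor specification
#'
#' @param regressor `"svr"` (support vector regression), `"rf"` (random
#'   forest), or `"xgb"` (gradient boosting).
#' @param feature_source `"gcn_features"` (learned pre-head features from
#'   [extract_drug_protein_features()]) or `"raw_tokens"` (concatenated
#'   SMILES and protein token vectors).
#' @param regressor_params Named list of hyperparameters passed through to
#'   the backing library (library defaults otherwise).
#' @param seed Integer seed for regressors with stochastic fitting.
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(regressor = c("svr", "rf", "xgb"),
                          feature_source = c("gcn_features", "raw_tokens"),
                          regressor_params = list(),
                          seed = 1L) {
  structure(
    list(
      regressor = match.arg(regressor),
      feature_source = match.arg(feature_source),
      regressor_params = regressor_params,
      seed = as.integer(seed)
    ),
    class = "baseline_spec"
  )
}

#' Raw token features for classical regressors
#'
#' Concatenates each record's SMILES character tokens (length `L_smiles`)
#' and protein tokens (length `L_protein`) into one numeric feature
#' vector — the "sequence format" baselines that need no learned feature
#' extraction.
#'
#' @param records Interaction table with `smiles` and `sequence` columns.
#' @param vocab A [protein_vocabulary()].
#' @param L_protein,L_smiles Token lengths.
#' @param smiles_vocab A [smiles_vocabulary()]; default built from the
#'   records.
#' @return Numeric matrix with `L_smiles + L_protein` columns.
#' @export
build_raw_features <- function(records, vocab = protein_vocabulary(),
                               L_protein = 1000L, L_smiles = 100L,
                               smiles_vocab = NULL) {
  smiles_vocab <- smiles_vocab %||% smiles_vocabulary(records$smiles)
  sm <- encode_smiles_matrix(records$smiles, smiles_vocab, L_smiles)
  pr <- t(vapply(
    records$sequence,
    function(s) encode_protein(s, vocab, L_protein)$tokens,
    integer(L_protein)
  ))
  out <- cbind(sm, pr)
  dimnames(out) <- NULL
  storage.mode(out) <- "double"
  out
}

#' Fit a baseline regressor
#'
#' Delegates to the backing library (e1071 for SVR, ranger for random
#' forests, xgboost for gradient boosting) with seeded determinism where
#' the regressor supports it.
#'
#' @param spec A [baseline_spec()].
#' @param features Numeric feature matrix (finite values).
#' @param labels Numeric response vector.
#' @return Object of class `dta_baseline` wrapping the fitted regressor.
#' @export
fit_baseline <- function(spec, features, labels) {
  if (!all(is.finite(features))) stop_invalid("features must be finite")
  if (nrow(features) != length(labels)) {
    stop_invalid("features and labels disagree in length")
  }
  if (stats::sd(labels) == 0) {
    # degenerate regression target: every backing library either errors
    # or wastes work here, so fit the (exact) constant predictor
    return(structure(
      list(spec = spec, fitted = labels[1], n_features = ncol(features),
           constant = TRUE),
      class = "dta_baseline"
    ))
  }
  pars <- spec$regressor_params
  fitted <- switch(spec$regressor,
    svr = do.call(e1071::svm, c(list(x = features, y = labels), pars)),
    rf = with_seed(spec$seed, do.call(ranger::ranger, c(
      list(
        x = as.data.frame(features), y = labels,
        seed = spec$seed, num.threads = 1
      ),
      pars
    ))),
    xgb = do.call(xgboost::xgboost, c(
      list(
        x = features, y = labels,
        nrounds = pars$nrounds %||% 100,
        verbosity = 0, nthreads = 1, seed = spec$seed
      ),
      pars[setdiff(names(pars), "nrounds")]
    ))
  )
  structure(
    list(spec = spec, fitted = fitted, n_features = ncol(features)),
    class = "dta_baseline"
  )
}

#' Predict with a fitted baseline
#'
#' @param object A `dta_baseline`.
#' @param features Feature matrix with the training column count.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.dta_baseline <- function(object, features, ...) {
  if (ncol(features) != object$n_features) {
    stop_invalid(sprintf(
      "feature count mismatch: model expects %d, got %d",
      object$n_features, ncol(features)
    ))
  }
  if (isTRUE(object$constant)) {
    return(rep(object$fitted, nrow(features)))
  }
  switch(object$spec$regressor,
    svr = as.numeric(stats::predict(object$fitted, features)),
    rf = as.numeric(stats::predict(object$fitted,
      data = as.data.frame(features),
      num.threads = 1
    )$predictions),
    xgb = as.numeric(stats::predict(object$fitted, features))
  )
}

#' Evaluate a fitted baseline on a test set
#'
#' @param fitted A `dta_baseline`.
#' @param features Test feature matrix.
#' @param labels Test labels.
#' @return A `dta_metrics` tibble (MSE, R-squared, concordance).
#' @export
evaluate_baseline <- function(fitted, features, labels) {
  evaluate(labels, predict(fitted, features))
}

#' Save / load a fitted baseline with its spec
#'
#' @param fitted A `dta_baseline`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_baseline <- function(fitted, path) {
  saveRDS(fitted, path)
  invisible(path)
}

#' @rdname save_baseline
#' @export
load_baseline <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "dta_baseline")) stop_config("not a baseline checkpoint")
  obj
}
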