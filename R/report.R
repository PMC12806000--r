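# Run reports: per-epoch logs, best-epoch summaries, serialization.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

utils::globalVariables(c("epoch", "value", "series"))

#' Build a run report from an epoch log
#'
#' A pure function of the log: the best epoch is the argmin of test MSE;
#' `metrics_at_best` are that epoch's metrics (primary reading of a "best
#' iteration"); `per_metric_bests` additionally tracks each metric's own
#' best over epochs (secondary reading).
#'
#' @param log Tibble with columns `epoch`, `train_loss`, `val_loss`,
#'   `test_mse`, `test_r2`, `test_ci`.
#' @param config Optional configuration echo stored with the report.
#' @return Object of class `dta_run_report` with `log`, `best_epoch`,
#'   `metrics_at_best`, `per_metric_bests`, `config`.
#' @export
run_report <- function(log, config = NULL) {
  stopifnot(all(c("epoch", "train_loss", "test_mse", "test_r2", "test_ci")
  %in% names(log)))
  best_epoch <- log$epoch[which.min(log$test_mse)]
  structure(
    list(
      log = log,
      best_epoch = best_epoch,
      metrics_at_best = log[log$epoch == best_epoch, ],
      per_metric_bests = tibble::tibble(
        metric = c("test_mse", "test_r2", "test_ci"),
        best = c(min(log$test_mse), max(log$test_r2), max(log$test_ci)),
        epoch = c(
          log$epoch[which.min(log$test_mse)],
          log$epoch[which.max(log$test_r2)],
          log$epoch[which.max(log$test_ci)]
        )
      ),
      config = config
    ),
    class = "dta_run_report"
  )
}

#' Write a run report to disk
#'
#' The epoch log goes to `log.jsonl` (one JSON object per epoch) and the
#' best-epoch summary plus configuration echo to `summary.json`.
#'
#' @param report A `dta_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "log.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(report$log))) {
    writeLines(jsonlite::toJSON(as.list(report$log[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
  jsonlite::write_json(
    list(
      best_epoch = report$best_epoch,
      metrics_at_best = as.list(report$metrics_at_best),
      per_metric_bests = report$per_metric_bests,
      config = .config_echo(report$config)
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# Configuration echo stripped to JSON-friendly atoms.
.config_echo <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  if (is.null(config)) NULL else strip(config)
}

#' Read an epoch log written by [write_run_report()]
#'
#' @param path Path to a `log.jsonl` file.
#' @return The epoch log as a tibble.
#' @export
read_epoch_log <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  })
  do.call(rbind, rows)
}

#' @export
print.dta_run_report <- function(x, ...) {
  m <- x$metrics_at_best
  cat(sprintf(
    "<dta_run_report> %d epochs; best epoch %d: test MSE %.4f, R2 %.4f, CI %.4f\n",
    nrow(x$log), x$best_epoch, m$test_mse, m$test_r2, m$test_ci
  ))
  invisible(x)
}

#' @export
print.dta_fit <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Training-curve plot for a run report
#'
#' Training and validation loss plus test MSE per epoch.
#'
#' @param object A `dta_run_report` (or `dta_fit`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dta_run_report <- function(object, ...) {
  log <- object$log
  long <- rbind(
    data.frame(epoch = log$epoch, value = log$train_loss, series = "train loss"),
    data.frame(epoch = log$epoch, value = log$val_loss, series = "val loss"),
    data.frame(epoch = log$epoch, value = log$test_mse, series = "test MSE")
  )
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss / MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dta_fit <- function(object, ...) autoplot.dta_run_report(object$report, ...)
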