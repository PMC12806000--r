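# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing validation errors in the package carry one of three
#' classes so callers (and the command-line driver) can map them to exit
#' codes: `dta_invalid_input` for bad data, `dta_config_error` for
#' inconsistent configuration, `dta_undefined_metric` for metrics that are
#' mathematically undefined on the given input.
#'
#' @noRd
dta_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_invalid <- function(msg, ...) dta_stop(msg, "dta_invalid_input", ...)
stop_config <- function(msg, ...) dta_stop(msg, "dta_config_error", ...)
stop_undefined <- function(msg, ...) dta_stop(msg, "dta_undefined_metric", ...)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
}

# Seeded evaluation that never disturbs the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
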