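# Evaluation metrics: MSE, coefficient of determination, concordance index.

#' Mean squared error
#'
#' @param y Observed values.
#' @param p Predicted values (same length).
#' @return `mean((p - y)^2)`.
#' @export
mse <- function(y, p) {
  if (length(y) != length(p)) stop_invalid("y and p must have equal length")
  if (length(y) < 1) stop_invalid("need at least one observation")
  mean((p - y)^2)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSR/SSM` where SSR is the sum of squared residuals about the
#' predictions and SSM the sum of squares about the mean of `y`.  Undefined
#' (an error, not silently 0) when `y` is constant.
#'
#' @inheritParams mse
#' @return R-squared (at most 1; can be negative for predictions worse
#'   than the mean).
#' @export
r2 <- function(y, p) {
  if (length(y) != length(p)) stop_invalid("y and p must have equal length")
  if (length(y) < 2) stop_invalid("need at least two observations")
  ssm <- sum((y - mean(y))^2)
  if (ssm == 0) stop_undefined("R-squared is undefined for constant y")
  1 - sum((y - p)^2) / ssm
}

# Fenwick (binary indexed) tree prefix-count helpers for the O(n log n)
# concordance index.
.fenwick_add <- function(tree, i) {
  n <- length(tree)
  while (i <= n) {
    tree[i] <- tree[i] + 1
    i <- i + bitwAnd(i, -i)
  }
  tree
}

.fenwick_query <- function(tree, i) {
  s <- 0
  while (i > 0) {
    s <- s + tree[i]
    i <- i - bitwAnd(i, -i)
  }
  s
}

#' Concordance index for regression
#'
#' Over all pairs with distinct labels (`y_i > y_j`), scores 1 when the
#' predictions agree in order (`p_i > p_j`), 0.5 when the predictions tie,
#' and 0 otherwise; label-tied pairs are excluded from the pair set.
#' Implemented by sorting plus order-statistic counting (O(n log n)).
#'
#' @inheritParams mse
#' @return Concordance index in `[0, 1]`; 0.5 is random ranking.
#' @export
concordance_index <- function(y, p) {
  if (length(y) != length(p)) stop_invalid("y and p must have equal length")
  n <- length(y)
  if (n < 2) stop_invalid("need at least two observations")
  if (all(y == y[1])) stop_undefined("concordance is undefined when all y are equal")

  ord <- order(y, p)
  y <- y[ord]
  p <- p[ord]
  p_rank <- match(p, sort(unique(p)))
  n_ranks <- max(p_rank)
  tree <- numeric(n_ranks)
  inserted <- 0L
  concordant <- 0
  pairs <- 0
  i <- 1L
  while (i <= n) {
    # process each group of equal y at once: compare against strictly
    # smaller labels only, then insert the whole group
    j <- i
    while (j <= n && y[j] == y[i]) j <- j + 1L
    for (k in i:(j - 1L)) {
      below <- .fenwick_query(tree, p_rank[k] - 1L)
      at <- .fenwick_query(tree, p_rank[k]) - below
      concordant <- concordant + below + 0.5 * at
      pairs <- pairs + inserted
    }
    for (k in i:(j - 1L)) tree <- .fenwick_add(tree, p_rank[k])
    inserted <- inserted + (j - i)
    i <- j
  }
  concordant / pairs
}

#' Evaluate predictions with all three metrics
#'
#' @inheritParams mse
#' @return A one-row tibble of class `dta_metrics` with columns `mse`,
#'   `r2`, `ci`, `n`.
#' @export
evaluate <- function(y, p) {
  out <- tibble::tibble(
    mse = mse(y, p),
    r2 = r2(y, p),
    ci = concordance_index(y, p),
    n = length(y)
  )
  class(out) <- c("dta_metrics", class(out))
  out
}
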