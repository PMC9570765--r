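#' Pearson correlation between actual and predicted potencies
#'
#' Direct evaluation of the product-moment formula
#' `sum((y - ybar)(p - pbar)) / sqrt(sum((y - ybar)^2) sum((p - pbar)^2))`.
#'
#' @param y,p Numeric vectors of equal length >= 2; both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(y, p) {
  check_pair(y, p, min_n = 2L)
  dy <- y - mean(y); dp <- p - mean(p)
  den <- sqrt(sum(dy^2) * sum(dp^2))
  if (den == 0) {
    abort("correlation undefined for a constant vector",
          class = "sibcut_error_degenerate")
  }
  sum(dy * dp) / den
}

#' Predictive r-squared
#'
#' `1 - sum((y - p)^2) / sum((y - ybar)^2)`: fraction of potency variance
#' explained by the predictions. Unlike squared correlation it penalizes
#' bias and scale errors, and can be negative on held-out data.
#'
#' @param y,p Numeric vectors of equal length >= 2; `y` non-constant.
#' @return A real number <= 1.
#' @export
predictive_r2 <- function(y, p) {
  check_pair(y, p, min_n = 2L)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    abort("predictive r2 undefined for constant actuals",
          class = "sibcut_error_degenerate")
  }
  1 - sum((y - p)^2) / tss
}

#' Root mean square error
#'
#' @param y,p Numeric vectors of equal length >= 1.
#' @return A nonnegative real number.
#' @export
rmse <- function(y, p) {
  check_pair(y, p, min_n = 1L)
  sqrt(mean((y - p)^2))
}

check_pair <- function(y, p, min_n) {
  if (length(y) != length(p)) {
    abort("actual and predicted vectors differ in length",
          class = "sibcut_error_contract")
  }
  if (length(y) < min_n) {
    abort(sprintf("need at least %d observations", min_n),
          class = "sibcut_error_contract")
  }
  if (any(!is.finite(y)) || any(!is.finite(p))) {
    abort("non-finite values in evaluation vectors",
          class = "sibcut_error_input")
  }
  invisible(TRUE)
}

#' Evaluate predictions against actual potencies
#'
#' @param y Actual potencies.
#' @param p Predicted potencies.
#' @return A one-row tibble with columns `r`, `r2`, `rmse`, `n`.
#' @export
evaluate_predictions <- function(y, p) {
  tibble(
    r = pearson_r(y, p),
    r2 = predictive_r2(y, p),
    rmse = rmse(y, p),
    n = length(y)
  )
}
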