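#' Validation statistics for paired ET series
#'
#' Five statistics compare an observed series (e.g. lysimeter daily ET)
#' with model estimates: the coefficient of determination, root mean
#' square error, Willmott's agreement index, the Nash-Sutcliffe model
#' efficiency and the mean bias error.
#'
#' @param observed,predicted Numeric vectors of equal length, mm day-1.
#' @name validation_stats
NULL

check_pairs <- function(observed, predicted, min_n = 1L) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted))
    stop("paired series must not contain missing values", call. = FALSE)
  if (length(observed) < min_n)
    stop("need at least ", min_n, " pairs", call. = FALSE)
  invisible(TRUE)
}

#' @rdname validation_stats
#' @details `r_squared()` is the squared Pearson correlation, written as
#'   the mean cross-product of deviations over the product of population
#'   standard deviations, squared.  Both series need nonzero variance.
#' @return `r_squared()`: R2 in `[0, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  check_pairs(observed, predicted, 2L)
  y <- observed; yh <- predicted
  sy <- sqrt(mean((y - mean(y))^2))
  syh <- sqrt(mean((yh - mean(yh))^2))
  if (sy == 0 || syh == 0)
    stop("R2 undefined for a constant series", call. = FALSE)
  (mean((y - mean(y)) * (yh - mean(yh))) / (sy * syh))^2
}

#' @rdname validation_stats
#' @details `rmse()` uses the `n` denominator.
#' @return `rmse()`: root mean square error, same units as the inputs.
#' @export
rmse <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname validation_stats
#' @details `agreement_index()` is Willmott's d:
#'   `d = 1 - sum((y - yhat)^2) / sum((|yhat - ybar| + |y - ybar|)^2)`,
#'   the square applied to each term of the denominator sum; 1 is a
#'   perfect match, 0 no match.
#' @return `agreement_index()`: d in `[0, 1]`.
#' @export
agreement_index <- function(observed, predicted) {
  check_pairs(observed, predicted, 2L)
  ybar <- mean(observed)
  den <- sum((abs(predicted - ybar) + abs(observed - ybar))^2)
  if (den == 0)
    stop("agreement index undefined: both series constant at the mean",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / den
}

#' @rdname validation_stats
#' @details `nsme()` is the Nash-Sutcliffe model efficiency
#'   `1 - sum((y - yhat)^2) / sum((y - ybar)^2)`, in `(-Inf, 1]`; 0 means
#'   the model is no better than the observed mean.
#' @return `nsme()`: efficiency, at most 1.
#' @export
nsme <- function(observed, predicted) {
  check_pairs(observed, predicted, 2L)
  den <- sum((observed - mean(observed))^2)
  if (den == 0)
    stop("NSME undefined for a constant observed series", call. = FALSE)
  1 - sum((observed - predicted)^2) / den
}

#' @rdname validation_stats
#' @details `mbe()` is the mean of `observed - predicted`.  Note the
#'   sign: with this convention a *negative* value means the model
#'   overestimates.
#' @return `mbe()`: mean bias error, same units as the inputs.
#' @export
mbe <- function(observed, predicted) {
  check_pairs(observed, predicted)
  mean(observed - predicted)
}

#' Full validation report for paired observed/estimated ET
#'
#' Computes all five statistics of [validation_stats] plus the pair
#' count.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`,
#'   mm day-1.
#' @param labels Optional per-pair identifiers (e.g. dates).
#' @return Object of class `et_validation`: list with `r2`, `rmse`, `d`,
#'   `nsme`, `mbe`, `n` and the inputs.
#' @examples
#' obs <- c(1.3, 1.6, 1.9, 2.3, 2.7, 3.0, 3.4, 3.7)
#' est <- obs + rnorm(8, 0, 0.2)
#' et_validation(obs, est)
#' @export
et_validation <- function(observed, predicted, labels = NULL) {
  check_pairs(observed, predicted, 2L)
  structure(
    list(r2 = r_squared(observed, predicted),
         rmse = rmse(observed, predicted),
         d = agreement_index(observed, predicted),
         nsme = nsme(observed, predicted),
         mbe = mbe(observed, predicted),
         n = length(observed),
         observed = observed, predicted = predicted, labels = labels),
    class = "et_validation"
  )
}

#' @export
print.et_validation <- function(x, digits = 3, ...) {
  cat(sprintf("ET validation on %d pairs\n", x$n))
  cat(sprintf("  R2    %.*f\n", digits, x$r2))
  cat(sprintf("  RMSE  %.*f mm/day\n", digits, x$rmse))
  cat(sprintf("  d     %.*f  (Willmott agreement)\n", digits, x$d))
  cat(sprintf("  NSME  %.*f\n", digits, x$nsme))
  cat(sprintf("  MBE   %.*f mm/day  (observed - predicted)\n",
              digits, x$mbe))
  invisible(x)
}
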