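#' Differentiation rate from callus counts
#'
#' `P = (omega0 - omega1) / omega0 * 100`, with `omega0` the number of
#' inoculated calluses and `omega1` the number that formed plantlets. The
#' formula is implemented exactly as conventionally printed; note its
#' labeling is debatable (it is the complement of the plantlet fraction),
#' so [plantlet_rate()] is provided as the explicit alternative.
#'
#' @param omega0 Number of inoculated calluses (> 0).
#' @param omega1 Number of calluses that differentiated (0 <= omega1 <= omega0).
#' @return Rate in percent.
#' @export
differentiation_rate <- function(omega0, omega1) {
  if (any(omega0 <= 0)) stop("division error: omega0 must be > 0")
  if (any(omega1 < 0) || any(omega1 > omega0))
    stop("domain error: need 0 <= omega1 <= omega0")
  (omega0 - omega1) / omega0 * 100
}

#' Plantlet formation rate
#'
#' `omega1 / omega0 * 100`: the fraction of inoculated calluses that formed
#' plantlets, in percent. Convenience complement of [differentiation_rate()].
#'
#' @inheritParams differentiation_rate
#' @return Rate in percent.
#' @export
plantlet_rate <- function(omega0, omega1) {
  if (any(omega0 <= 0)) stop("division error: omega0 must be > 0")
  if (any(omega1 < 0) || any(omega1 > omega0))
    stop("domain error: need 0 <= omega1 <= omega0")
  omega1 / omega0 * 100
}

check_rate_pair <- function(target, predicted, scale) {
  if (length(target) != length(predicted))
    stop("dimension error: target and predicted lengths differ (",
         length(target), " vs ", length(predicted), ")")
  if (length(target) < 2) stop("need at least 2 paired values")
  scale
}

rescale_pair <- function(x, scale) if (scale == "proportion") x / 100 else x

#' Mean squared error between target and predicted rates
#'
#' `MSE = (1/n) * sum((P_i - Phat_i)^2)`. Rates held in percent can be scored
#' on the proportion scale by passing `scale = "proportion"`, which divides
#' both vectors by 100 first; this is the convention under which the melon
#' study's headline RMSE of 0.0108 arises from percent-valued tables.
#'
#' @param target Actual rates, percent units.
#' @param predicted Predicted rates, percent units.
#' @param scale `"percent"` (score as given) or `"proportion"` (divide by 100).
#' @return Mean squared error on the requested scale.
#' @export
mse <- function(target, predicted, scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  check_rate_pair(target, predicted, scale)
  t <- rescale_pair(target, scale)
  p <- rescale_pair(predicted, scale)
  mean((t - p)^2)
}

#' Root mean squared error
#'
#' `RMSE = sqrt(MSE)`; see [mse()] for the scale convention.
#'
#' @inheritParams mse
#' @return RMSE on the requested scale.
#' @examples
#' t1 <- load_table1()
#' rmse(t1$observed, t1$paper_predicted, scale = "proportion")  # 0.0108
#' @export
rmse <- function(target, predicted, scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  sqrt(mse(target, predicted, scale = scale))
}

#' Squared Pearson correlation between target and predicted rates
#'
#' The squared sample product-moment correlation, invariant to affine
#' changes of either vector (hence to the percent/proportion choice).
#'
#' @inheritParams mse
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(target, predicted) {
  check_rate_pair(target, predicted, "percent")
  if (stats::sd(target) == 0 || stats::sd(predicted) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(target, predicted)^2
}

#' Relative error in percent
#'
#' `E(%) = |predicted - actual| / actual * 100`, the discrepancy measure used
#' to compare a surrogate-predicted optimum against wet-lab validation runs.
#'
#' @param predicted Predicted value.
#' @param actual Reference value (nonzero).
#' @return Relative error in percent.
#' @examples
#' relative_error_pct(91.97, 90.53)  # 1.59
#' @export
relative_error_pct <- function(predicted, actual) {
  if (any(actual == 0)) stop("division error: actual must be nonzero")
  abs(predicted - actual) / actual * 100
}
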