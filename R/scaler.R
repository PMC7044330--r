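#' Fit a per-column min-max scaler to [-1, 1]
#'
#' Linear map of each column's observed `[min, max]` onto `[-1, 1]`, the
#' normalization convention of classic feedforward-network toolboxes (tansig
#' saturates on raw percent or degree-Celsius scales). The inverse transform
#' is exact.
#'
#' @param x Numeric vector or matrix (columns are variables).
#' @return An object of class `minmax_scaler` with fields `min` and `max`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  if (any(mx <= mn))
    stop("degenerate scaler: constant variable (min == max)")
  structure(list(min = mn, max = mx), class = "minmax_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler A `minmax_scaler`.
#' @param x Vector or matrix on the original scale.
#' @return `x` mapped onto `[-1, 1]` (columns outside the fitted range map
#'   outside `[-1, 1]`; the map is affine, not clipping).
#' @export
scaler_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vec <- !is.matrix(x)
  x <- if (vec) matrix(x, nrow = 1) else x
  out <- sweep(sweep(x, 2, scaler$min, `-`), 2, scaler$max - scaler$min, `/`) * 2 - 1
  if (vec) drop(out) else out
}

#' Invert a fitted scaler
#'
#' @param scaler A `minmax_scaler`.
#' @param x Vector or matrix on the `[-1, 1]` scale.
#' @return `x` mapped back to the original scale.
#' @export
scaler_invert <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vec <- !is.matrix(x)
  x <- if (vec) matrix(x, nrow = 1) else x
  out <- sweep(sweep((x + 1) / 2, 2, scaler$max - scaler$min, `*`), 2, scaler$min, `+`)
  if (vec) drop(out) else out
}
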