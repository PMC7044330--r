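#' Draw a random smooth response surface for simulation
#'
#' Generates a concave quadratic surface in k coded factors whose maximum
#' lies inside (or, with probability ~0.3, on the boundary of) the coded
#' box, with a peak response drawn in 80-95% — the regime of a
#' differentiation-rate experiment. The Hessian has eigenvalues in roughly
#' [-3, -0.2] (% per coded-unit squared), giving surfaces whose response
#' drops by tens of points across the box, as the melon data do.
#'
#' @param seed Integer seed; the spec is reproducible.
#' @param k Number of coded factors (default 4).
#' @param noise_sd Observation noise standard deviation in percent units
#'   (default 1, the replicate scatter scale of validation runs).
#' @param bounds 2-row matrix of the coded box (default `[-2, 2]^k`).
#' @return Object of class `surface_spec`: `model` (`quadratic_model`),
#'   `noise_sd`, `floor`, `ceiling`, `optimum` (list `point`, `value`),
#'   `seed`, `bounds`.
#' @export
sample_surface_spec <- function(seed = 1L, k = 4L, noise_sd = 1,
                                bounds = matrix(c(-2, 2), 2, k)) {
  stopifnot(noise_sd >= 0, k >= 2)
  withr::with_seed(as.integer(seed), {
    # negative-definite Hessian with controlled spectrum
    A <- matrix(stats::rnorm(k * k), k, k)
    S <- crossprod(A)
    ev <- eigen(S, symmetric = TRUE)
    lam <- stats::runif(k, 0.2, 3)
    H <- -ev$vectors %*% diag(lam) %*% t(ev$vectors)
    boundary <- stats::runif(1) < 0.3
    x_star <- stats::runif(k, -1.8, 1.8)
    if (boundary) {
      j <- sample.int(k, 1)
      x_star[j] <- sample(c(bounds[1, j], bounds[2, j]), 1)
    }
    f_max <- stats::runif(1, 80, 95)
    # f(x) = f_max + 0.5 (x - x*)' H (x - x*)  =  c + b'x + x'Qx
    Q <- H / 2
    b <- as.numeric(-H %*% x_star)
    cc <- f_max + 0.5 * as.numeric(t(x_star) %*% H %*% x_star)
    pairs <- interaction_pairs(k)
    model <- quadratic_model(cc, b, diag(Q),
                             if (nrow(pairs)) 2 * Q[pairs] else numeric(0))
    structure(list(model = model, noise_sd = noise_sd, floor = 0, ceiling = 100,
                   optimum = list(point = x_star, value = f_max),
                   seed = as.integer(seed), bounds = bounds),
              class = "surface_spec")
  })
}

#' Simulate observed rates on a design from a surface spec
#'
#' `response = clip(truth(coded) + N(0, noise_sd), floor, ceiling)`.
#'
#' @param spec A `surface_spec`.
#' @param design A `ccd_table` (responses, if any, are ignored).
#' @param seed Seed for the noise draw; defaults to `spec$seed`.
#' @return A `ccd_table` with simulated `observed` rates (% scale).
#' @export
generate_dataset <- function(spec, design, seed = spec$seed) {
  stopifnot(inherits(spec, "surface_spec"), inherits(design, "ccd_table"))
  truth <- predict_quadratic(spec$model, design$coded)
  noise <- if (spec$noise_sd > 0)
    withr::with_seed(as.integer(seed),
                     stats::rnorm(length(truth), 0, spec$noise_sd))
  else rep(0, length(truth))
  y <- pmin(pmax(truth + noise, spec$floor), spec$ceiling)
  ccd_table(design$coded, design$factors, observed = y)
}

#' True box-constrained optimum of a surface spec
#'
#' Returns the analytic stationary point when it is an interior maximum of
#' the concave quadratic; otherwise falls back to the dense-grid + polish
#' search of [maximize_quadratic()]. Serves as the oracle for end-to-end
#' recovery tests.
#'
#' @param spec A `surface_spec`.
#' @param bounds Coded box; defaults to `spec$bounds`.
#' @return List with `point` and `value`.
#' @export
true_optimum <- function(spec, bounds = spec$bounds) {
  stopifnot(inherits(spec, "surface_spec"))
  m <- spec$model
  k <- m$k
  Q <- diag(m$pure_quadratic, k)
  pairs <- interaction_pairs(k)
  for (p in seq_len(nrow(pairs))) {
    Q[pairs[p, 1], pairs[p, 2]] <- m$interaction[p] / 2
    Q[pairs[p, 2], pairs[p, 1]] <- m$interaction[p] / 2
  }
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev < 0)) {
    xs <- as.numeric(solve(2 * Q, -m$linear))   # gradient b + 2 Q x = 0
    if (all(xs >= bounds[1, ] & xs <= bounds[2, ]))
      return(list(point = xs, value = predict_quadratic(m, xs)))
  }
  maximize_quadratic(m, bounds)
}

#' Serialize a surface spec to JSON
#'
#' @param spec A `surface_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_spec_json <- function(spec, path) {
  obj <- list(model = unclass(spec$model), noise_sd = spec$noise_sd,
              floor = spec$floor, ceiling = spec$ceiling,
              optimum = spec$optimum, seed = spec$seed,
              bounds = list(lower = spec$bounds[1, ], upper = spec$bounds[2, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
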