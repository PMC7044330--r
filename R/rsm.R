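#' Construct a full second-order polynomial model on coded factors
#'
#' Coefficient layout for k factors: intercept, k linear terms, k pure
#' quadratic terms, and the k(k-1)/2 pairwise interactions in lexicographic
#' order (1,2), (1,3), ..., (k-1,k) — 15 coefficients for the four-factor
#' melon design.
#'
#' @param intercept Intercept.
#' @param linear Numeric vector of length k.
#' @param pure_quadratic Numeric vector of length k.
#' @param interaction Numeric vector of length k(k-1)/2, lexicographic pairs.
#' @param r_squared Optional fit R-squared to carry along.
#' @return Object of class `quadratic_model`.
#' @export
quadratic_model <- function(intercept, linear, pure_quadratic, interaction,
                            r_squared = NULL) {
  k <- length(linear)
  stopifnot(length(pure_quadratic) == k, length(interaction) == k * (k - 1) / 2,
            all(is.finite(c(intercept, linear, pure_quadratic, interaction))))
  structure(list(intercept = as.numeric(intercept), linear = as.numeric(linear),
                 pure_quadratic = as.numeric(pure_quadratic),
                 interaction = as.numeric(interaction), k = k,
                 r_squared = r_squared),
            class = "quadratic_model")
}

interaction_pairs <- function(k) {
  if (k < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(k, 2))
}

# model matrix of the full quadratic: 1 | x | x^2 | x_i x_j (i<j)
quadratic_design_matrix <- function(X) {
  k <- ncol(X)
  pairs <- interaction_pairs(k)
  inter <- if (nrow(pairs)) {
    m <- matrix(0, nrow(X), nrow(pairs))
    for (p in seq_len(nrow(pairs))) m[, p] <- X[, pairs[p, 1]] * X[, pairs[p, 2]]
    m
  } else NULL
  M <- cbind(1, X, X^2, inter)
  colnames(M) <- c("(Intercept)", paste0("x", seq_len(k)),
                   paste0("x", seq_len(k), "^2"),
                   if (nrow(pairs)) paste0("x", pairs[, 1], ":x", pairs[, 2]))
  M
}

#' Fit the full-quadratic response surface by OLS
#'
#' Ordinary least squares of the observed response on the intercept, linear,
#' pure-quadratic and pairwise-interaction terms of the coded factors — the
#' standard central-composite-design response-surface fit. The fit is
#' delegated to [stats::lm()].
#'
#' @param data A `ccd_table` with observed rates, or a list with elements
#'   `coded` (matrix) and `observed` (vector).
#' @return A `quadratic_model` with `r_squared = 1 - SSE/SST` attached.
#' @examples
#' fit <- fit_full_quadratic(load_table1())
#' round(fit$r_squared, 4)
#' @export
fit_full_quadratic <- function(data) {
  X <- as.matrix(data$coded)
  y <- data$observed
  if (is.null(y)) stop("data has no observed response")
  k <- ncol(X)
  n_coef <- 1 + 2 * k + k * (k - 1) / 2
  if (nrow(X) <= n_coef)
    stop("need more runs (", nrow(X), ") than coefficients (", n_coef, ")")
  M <- quadratic_design_matrix(X)
  df <- as.data.frame(M[, -1, drop = FALSE])
  names(df) <- paste0("t", seq_len(ncol(df)))   # syntactic names for lm
  df$y <- y
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: full-quadratic model is rank deficient")
  beta <- unname(stats::coef(fit))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  quadratic_model(beta[1], beta[2:(k + 1)], beta[(k + 2):(2 * k + 1)],
                  beta[(2 * k + 2):n_coef], r_squared = r2)
}

#' Evaluate a quadratic model at coded points
#'
#' @param model A `quadratic_model`.
#' @param x Coded point (vector) or matrix of points (rows).
#' @return Predicted response(s), percent scale.
#' @export
predict_quadratic <- function(model, x) {
  stopifnot(inherits(model, "quadratic_model"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$k)
    stop("dimension error: point has ", ncol(X), " coordinates, expected ", model$k)
  M <- quadratic_design_matrix(X)
  beta <- c(model$intercept, model$linear, model$pure_quadratic, model$interaction)
  drop(M %*% beta)
}

#' Box-constrained maximum of a quadratic model
#'
#' Dense grid search over the box followed by an L-BFGS-B polish from the
#' best grid point ([stats::optim()]); deterministic.
#'
#' @param model A `quadratic_model`.
#' @param bounds 2-row matrix `rbind(lower, upper)` per dimension.
#' @param grid_points Grid resolution per dimension (default 11).
#' @return List with `point` (coded argmax) and `value`.
#' @export
maximize_quadratic <- function(model, bounds = matrix(c(-2, 2), 2, 4),
                               grid_points = 11L) {
  stopifnot(inherits(model, "quadratic_model"), nrow(bounds) == 2,
            ncol(bounds) == model$k)
  grids <- lapply(seq_len(model$k), function(i)
    seq(bounds[1, i], bounds[2, i], length.out = grid_points))
  G <- as.matrix(expand.grid(grids))
  dimnames(G) <- NULL
  vals <- predict_quadratic(model, G)
  x0 <- G[which.max(vals), ]
  opt <- stats::optim(x0, function(x) -predict_quadratic(model, x),
                      method = "L-BFGS-B",
                      lower = bounds[1, ], upper = bounds[2, ])
  if (-opt$value >= max(vals)) list(point = unname(opt$par), value = -opt$value)
  else list(point = x0, value = max(vals))
}

#' Serialize a quadratic model to JSON
#'
#' @param model A `quadratic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quadratic_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a quadratic model serialized by [write_quadratic_json()]
#'
#' @param path JSON file path.
#' @return A `quadratic_model`.
#' @export
read_quadratic_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  quadratic_model(obj$intercept, obj$linear, obj$pure_quadratic,
                  obj$interaction, r_squared = obj$r_squared)
}

#' Coefficient table of a quadratic model
#'
#' @param model A `quadratic_model`.
#' @return `data.frame` with columns `term`, `estimate`.
#' @export
quadratic_coef_table <- function(model) {
  k <- model$k
  pairs <- interaction_pairs(k)
  data.frame(
    term = c("(Intercept)", paste0("x", seq_len(k)), paste0("x", seq_len(k), "^2"),
             paste0("x", pairs[, 1], ":x", pairs[, 2])),
    estimate = c(model$intercept, model$linear, model$pure_quadratic,
                 model$interaction)
  )
}
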