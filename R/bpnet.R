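#' Network architecture descriptor
#'
#' Three-layer feedforward network: tan-sigmoid hidden layer, linear output.
#' The surrogate used throughout is 4 inputs, a selected hidden width
#' (3 for the melon study), 1 output.
#'
#' @param n_in Number of inputs (>= 1).
#' @param n_hidden Hidden-layer width (>= 1).
#' @param n_out Number of outputs (>= 1).
#' @return Object of class `bp_arch`.
#' @export
bp_arch <- function(n_in, n_hidden, n_out = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = as.integer(n_out)),
            class = "bp_arch")
}

#' Training configuration for the backpropagation trainers
#'
#' Defaults follow the de-facto conventions for batch gradient descent with
#' momentum and an adaptive learning rate (`gdx`): after an epoch whose MSE
#' worsens by more than `max_perf_increase`-fold the step is discarded, the
#' learning rate is multiplied by `lr_decrease`, and momentum is suppressed
#' for the next step; after an improving epoch the rate is multiplied by
#' `lr_increase`.
#'
#' @param algorithm One of `"gd"` (plain gradient descent), `"gdm"`
#'   (momentum), `"gda"` (adaptive rate), `"gdx"` (momentum + adaptive rate),
#'   `"lm"` (Levenberg-Marquardt).
#' @param learning_rate Initial learning rate (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param lr_increase Rate multiplier after improving epochs (> 1).
#' @param lr_decrease Rate multiplier after rejected epochs, in `(0, 1)`.
#' @param max_perf_increase Tolerated MSE worsening factor (> 1).
#' @param max_epochs Maximum number of batch epochs.
#' @param goal_mse Stop once the training MSE reaches this value.
#' @param min_gradient Stop once the gradient norm falls below this value.
#' @param mu,mu_decrease,mu_increase,mu_max Levenberg-Marquardt damping
#'   schedule (initial value, multiplier on accepted / rejected steps, cap).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `train_config`.
#' @export
train_config <- function(algorithm = c("gdx", "gd", "gdm", "gda", "lm"),
                         learning_rate = 0.01, momentum = 0.9,
                         lr_increase = 1.05, lr_decrease = 0.7,
                         max_perf_increase = 1.04,
                         max_epochs = 1000L, goal_mse = 0,
                         min_gradient = 1e-6,
                         mu = 1e-3, mu_decrease = 0.1, mu_increase = 10,
                         mu_max = 1e10, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            lr_increase > 1, lr_decrease > 0, lr_decrease < 1,
            max_perf_increase > 1, max_epochs >= 1, goal_mse >= 0,
            min_gradient >= 0, mu > 0)
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 momentum = momentum, lr_increase = lr_increase,
                 lr_decrease = lr_decrease, max_perf_increase = max_perf_increase,
                 max_epochs = as.integer(max_epochs), goal_mse = goal_mse,
                 min_gradient = min_gradient, mu = mu, mu_decrease = mu_decrease,
                 mu_increase = mu_increase, mu_max = mu_max,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network weights
#'
#' Hidden-layer rows are drawn uniform and rescaled to the Nguyen-Widrow
#' magnitude `0.7 * n_hidden^(1/n_in)` with biases spread across the active
#' input region; the output layer is small uniform. Reproducible per seed.
#'
#' @param arch A `bp_arch`.
#' @param seed Integer seed.
#' @return Object of class `bp_weights` with `W1` (`n_hidden x n_in`), `b1`,
#'   `W2` (`n_out x n_hidden`), `b2`.
#' @export
init_weights <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "bp_arch"))
  withr::with_seed(as.integer(seed), {
    h <- arch$n_hidden; k <- arch$n_in; m <- arch$n_out
    W1 <- matrix(stats::runif(h * k, -0.5, 0.5), h, k)
    norms <- sqrt(rowSums(W1^2))
    norms[norms == 0] <- 1
    beta <- 0.7 * h^(1 / k)
    W1 <- W1 * beta / norms
    b1 <- if (h == 1) 0 else seq(-1, 1, length.out = h) * beta
    b1 <- b1 * sign(stats::runif(h) - 0.5)
    W2 <- matrix(stats::runif(m * h, -0.5, 0.5), m, h)
    b2 <- stats::runif(m, -0.5, 0.5)
    structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2)),
              class = "bp_weights")
  })
}

check_bp_shapes <- function(weights, X) {
  if (ncol(X) != ncol(weights$W1))
    stop("dimension error: X has ", ncol(X), " columns but the network expects ",
         ncol(weights$W1), " inputs")
}

#' Forward pass of the three-layer network
#'
#' `yhat = W2 %*% tanh(W1 %*% x + b1) + b2` per row of `X`; tan-sigmoid is
#' `2/(1+exp(-2x)) - 1 = tanh(x)`.
#'
#' @param weights A `bp_weights`.
#' @param X Matrix of (scaled) inputs, one row per case.
#' @return Matrix of outputs, `nrow(X) x n_out`.
#' @export
bp_forward <- function(weights, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  check_bp_shapes(weights, X)
  A1 <- tanh(sweep(X %*% t(weights$W1), 2, weights$b1, `+`))
  sweep(A1 %*% t(weights$W2), 2, weights$b2, `+`)
}

#' Exact gradient of the mean-squared-error loss
#'
#' Backpropagated gradient of `(1/n) * sum((y - yhat)^2)` (summed over
#' outputs, averaged over cases) with respect to every weight and bias.
#'
#' @param weights A `bp_weights`.
#' @param X Input matrix, one row per case.
#' @param y Target matrix or vector.
#' @return List shaped like `bp_weights` (`W1`, `b1`, `W2`, `b2`).
#' @export
bp_gradient <- function(weights, X, y) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  y <- if (is.matrix(y)) y else matrix(y, ncol = nrow(weights$W2))
  check_bp_shapes(weights, X)
  if (nrow(y) != nrow(X)) stop("dimension error: X and y case counts differ")
  n <- nrow(X)
  A1 <- tanh(sweep(X %*% t(weights$W1), 2, weights$b1, `+`))
  Yhat <- sweep(A1 %*% t(weights$W2), 2, weights$b2, `+`)
  dY <- (Yhat - y) * (2 / n)          # dL/dYhat
  gW2 <- t(dY) %*% A1
  gb2 <- colSums(dY)
  dZ1 <- (dY %*% weights$W2) * (1 - A1^2)
  gW1 <- t(dZ1) %*% X
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

bp_mse <- function(weights, X, y) {
  r <- bp_forward(weights, X) - (if (is.matrix(y)) y else matrix(y, ncol = nrow(weights$W2)))
  mean(rowSums(r^2))
}

grad_norm <- function(g) sqrt(sum(g$W1^2) + sum(g$b1^2) + sum(g$W2^2) + sum(g$b2^2))

# flatten/unflatten parameters for the Levenberg-Marquardt normal equations
flatten_weights <- function(w) c(as.numeric(w$W1), w$b1, as.numeric(w$W2), w$b2)
unflatten_weights <- function(theta, arch) {
  h <- arch$n_hidden; k <- arch$n_in; m <- arch$n_out
  i <- 0
  W1 <- matrix(theta[i + seq_len(h * k)], h, k); i <- i + h * k
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(m * h)], m, h); i <- i + m * h
  b2 <- theta[i + seq_len(m)]
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2), class = "bp_weights")
}

# Jacobian of the single-output prediction wrt all parameters, n x p
bp_jacobian <- function(weights, X) {
  n <- nrow(X); h <- nrow(weights$W1); k <- ncol(weights$W1)
  A1 <- tanh(sweep(X %*% t(weights$W1), 2, weights$b1, `+`))
  D <- (1 - A1^2) * matrix(weights$W2[1, ], n, h, byrow = TRUE)  # dyhat/dz1
  JW1 <- matrix(0, n, h * k)
  for (j in seq_len(k)) JW1[, (j - 1) * h + seq_len(h)] <- D * X[, j]
  cbind(JW1, D, A1, rep(1, n))
}

#' Train the network by batch backpropagation
#'
#' Full-batch training with one of five update rules: plain gradient descent
#' (`gd`), gradient descent with momentum (`gdm`), adaptive learning rate
#' without momentum (`gda`), momentum plus adaptive learning rate (`gdx`),
#' or Levenberg-Marquardt damped Gauss-Newton (`lm`, single-output only).
#' Stops at `goal_mse`, `max_epochs`, or `min_gradient`. Inputs and targets
#' are expected on the `[-1, 1]` scale (see [fit_scaler()]).
#'
#' @param arch A `bp_arch`.
#' @param X Scaled input matrix.
#' @param y Scaled target vector/matrix.
#' @param config A `train_config`.
#' @return Object of class `train_record`: `weights`, `epoch_mse`,
#'   `stop_reason` (one of `"goal"`, `"max_epochs"`, `"min_gradient"`),
#'   `final_mse`, `learning_rates` (per-epoch trajectory), `config`.
#' @export
bp_train <- function(arch, X, y, config = train_config()) {
  stopifnot(inherits(arch, "bp_arch"), inherits(config, "train_config"))
  X <- as.matrix(X)
  y <- if (is.matrix(y)) y else matrix(y, ncol = arch$n_out)
  if (config$algorithm == "lm" && arch$n_out != 1)
    stop("lm trainer supports single-output networks only")
  w <- init_weights(arch, config$seed)
  alg <- config$algorithm
  lr <- config$learning_rate
  mu <- config$mu
  vel <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = w$b2 * 0)
  suppress_momentum <- FALSE
  prev_mse <- bp_mse(w, X, y)
  epoch_mse <- numeric(0)
  lrs <- numeric(0)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    if (alg == "lm") {
      r <- as.numeric(y) - as.numeric(bp_forward(w, X))
      J <- bp_jacobian(w, X)
      g2JtR <- crossprod(J, r)
      if (sqrt(sum((2 * g2JtR / length(r))^2)) < config$min_gradient) {
        stop_reason <- "min_gradient"; break
      }
      JtJ <- crossprod(J)
      accepted <- FALSE
      while (!accepted && mu <= config$mu_max) {
        step <- tryCatch(solve(JtJ + mu * diag(ncol(J)), g2JtR),
                         error = function(e) NULL)
        if (!is.null(step)) {
          w_new <- unflatten_weights(flatten_weights(w) + as.numeric(step), arch)
          new_mse <- bp_mse(w_new, X, y)
          if (is.finite(new_mse) && new_mse < prev_mse) {
            w <- w_new; prev_mse <- new_mse
            mu <- max(mu * config$mu_decrease, 1e-20)
            accepted <- TRUE
          } else mu <- mu * config$mu_increase
        } else mu <- mu * config$mu_increase
      }
      if (!accepted) { stop_reason <- "min_gradient"; break }
    } else {
      g <- bp_gradient(w, X, y)
      gn <- grad_norm(g)
      if (!is.finite(gn)) stop("divergence error at epoch ", epoch, ": non-finite gradient")
      if (gn < config$min_gradient) { stop_reason <- "min_gradient"; break }
      mc <- if (alg %in% c("gdm", "gdx") && !suppress_momentum) config$momentum else 0
      step <- list(W1 = mc * vel$W1 - lr * g$W1, b1 = mc * vel$b1 - lr * g$b1,
                   W2 = mc * vel$W2 - lr * g$W2, b2 = mc * vel$b2 - lr * g$b2)
      w_new <- structure(list(W1 = w$W1 + step$W1, b1 = w$b1 + step$b1,
                              W2 = w$W2 + step$W2, b2 = w$b2 + step$b2),
                         class = "bp_weights")
      new_mse <- bp_mse(w_new, X, y)
      if (!is.finite(new_mse)) stop("divergence error at epoch ", epoch, ": non-finite loss")
      if (alg %in% c("gda", "gdx") && new_mse > config$max_perf_increase * prev_mse) {
        # reject: keep old weights, shrink rate, kill momentum for next step
        lr <- lr * config$lr_decrease
        vel <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = w$b2 * 0)
        suppress_momentum <- TRUE
      } else {
        if (alg %in% c("gda", "gdx") && new_mse < prev_mse)
          lr <- lr * config$lr_increase
        w <- w_new; vel <- step; prev_mse <- new_mse
        suppress_momentum <- FALSE
      }
    }
    epoch_mse <- c(epoch_mse, prev_mse)
    lrs <- c(lrs, lr)
    if (prev_mse <= config$goal_mse) { stop_reason <- "goal"; break }
  }
  if (length(epoch_mse) == 0) { epoch_mse <- prev_mse; lrs <- lr }
  structure(list(weights = w, epoch_mse = epoch_mse, stop_reason = stop_reason,
                 final_mse = prev_mse, learning_rates = lrs, config = config),
            class = "train_record")
}

#' Fit a complete surrogate network on a CCD dataset
#'
#' Fits input/output min-max scalers, trains with best-of-`restarts`
#' initializations (selected by final training MSE), and returns a
#' self-contained predictor on the percent scale.
#'
#' @param data A `ccd_table` with `observed` rates.
#' @param n_hidden Hidden-layer width.
#' @param config A `train_config`; its `seed` seeds restart `1`, restart `r`
#'   uses `seed + r - 1`.
#' @param restarts Number of seeded restarts (>= 1).
#' @return Object of class `bp_net`: `arch`, `weights`, `x_scaler`,
#'   `y_scaler`, `record` (winning `train_record`), `restart_mse`.
#' @export
fit_bp_surrogate <- function(data, n_hidden = 3, config = train_config(),
                             restarts = 10) {
  stopifnot(inherits(data, "ccd_table"), !is.null(data$observed), restarts >= 1)
  arch <- bp_arch(ncol(data$coded), n_hidden, 1L)
  xs <- fit_scaler(data$coded)
  ys <- fit_scaler(matrix(data$observed, ncol = 1))
  Xs <- scaler_apply(xs, data$coded)
  yn <- scaler_apply(ys, matrix(data$observed, ncol = 1))
  best <- NULL
  restart_mse <- numeric(restarts)
  for (r in seq_len(restarts)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    rec <- bp_train(arch, Xs, yn, cfg)
    restart_mse[r] <- rec$final_mse
    if (is.null(best) || rec$final_mse < best$final_mse) best <- rec
  }
  structure(list(arch = arch, weights = best$weights, x_scaler = xs,
                 y_scaler = ys, record = best, restart_mse = restart_mse),
            class = "bp_net")
}

#' Predict percent-scale rates from a fitted surrogate
#'
#' @param object A `bp_net` from [fit_bp_surrogate()].
#' @param newdata Matrix (or vector) of coded design points.
#' @param ... Unused.
#' @return Numeric vector of predicted rates in percent.
#' @export
predict.bp_net <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  out <- bp_forward(object$weights, scaler_apply(object$x_scaler, X))
  as.numeric(scaler_invert(object$y_scaler, out))
}

#' @export
print.bp_net <- function(x, ...) {
  cat(sprintf("<bp_net> %d-%d-%d (tansig/linear), trainer %s, training MSE %.4g (scaled)\n",
              x$arch$n_in, x$arch$n_hidden, x$arch$n_out,
              x$record$config$algorithm, x$record$final_mse))
  invisible(x)
}

mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))

#' Serialize a fitted surrogate to JSON
#'
#' Row-major nested arrays with an architecture header and the scaler
#' parameters, so a trained surrogate is portable across sessions.
#'
#' @param net A `bp_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bp_net <- function(net, path) {
  stopifnot(inherits(net, "bp_net"))
  obj <- list(
    arch = list(n_in = net$arch$n_in, n_hidden = net$arch$n_hidden,
                n_out = net$arch$n_out),
    weights = list(W1 = mat_rows(net$weights$W1),
                   b1 = net$weights$b1,
                   W2 = mat_rows(net$weights$W2),
                   b2 = net$weights$b2),
    x_scaler = list(min = unname(net$x_scaler$min), max = unname(net$x_scaler$max)),
    y_scaler = list(min = unname(net$y_scaler$min), max = unname(net$y_scaler$max))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a surrogate serialized by [write_bp_net()]
#'
#' @param path JSON file path.
#' @return A `bp_net` (without a training record).
#' @export
read_bp_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  arch <- bp_arch(obj$arch$n_in, obj$arch$n_hidden, obj$arch$n_out)
  row_bind <- function(rows) do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  W1 <- row_bind(obj$weights$W1)
  W2 <- row_bind(obj$weights$W2)
  w <- structure(list(W1 = W1, b1 = as.numeric(obj$weights$b1),
                      W2 = W2, b2 = as.numeric(obj$weights$b2)),
                 class = "bp_weights")
  xs <- structure(list(min = as.numeric(obj$x_scaler$min),
                       max = as.numeric(obj$x_scaler$max)), class = "minmax_scaler")
  ys <- structure(list(min = as.numeric(obj$y_scaler$min),
                       max = as.numeric(obj$y_scaler$max)), class = "minmax_scaler")
  structure(list(arch = arch, weights = w, x_scaler = xs, y_scaler = ys,
                 record = NULL, restart_mse = NULL),
            class = "bp_net")
}
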