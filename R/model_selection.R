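#' Cross-validation plan
#'
#' Repeated k-fold: each repeat draws a fresh seeded partition; fold scores
#' are pooled into a per-repeat held-out MSE and repeats are averaged.
#'
#' @param k Number of folds (default 10).
#' @param repeats Number of independent repetitions (default 10).
#' @param seed Integer seed; repeat `r` partitions with `seed + r`.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(k = 10L, repeats = 10L, seed = 1L) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Shuffled k-fold partition of n indices
#'
#' @param n Number of cases.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` integer index vectors: a disjoint cover of `1..n`
#'   with fold sizes differing by at most 1.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k > n) stop("infeasible split: k = ", k, " exceeds n = ", n)
  if (k < 2) stop("infeasible split: k must be >= 2")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' Repeated k-fold cross-validation of a surrogate configuration
#'
#' For each repeat a fresh partition is drawn; for each fold the network is
#' trained on the remaining folds (scalers fitted on the training folds
#' only), the held-out rows are predicted, and squared errors are pooled
#' into the repeat's MSE. A fold whose training diverges is scored with the
#' training-target variance (the predict-the-mean baseline) instead of
#' aborting the selection; such folds are counted in `n_divergent`.
#'
#' @param arch A `bp_arch`.
#' @param config A `train_config`; fold `(r, f)` trains with seed
#'   `config$seed + 97 * r + f`.
#' @param data A `ccd_table` with observed rates.
#' @param plan A `cv_plan`.
#' @param scale Scale on which held-out MSE is computed: `"proportion"`
#'   (rates / 100, the study's MSE convention) or `"percent"`.
#' @param label Candidate label stored on the result.
#' @return Object of class `cv_result`: `label`, `mean_mse`, `repeat_mse`,
#'   `n_divergent`.
#' @export
cross_validate <- function(arch, config, data, plan = cv_plan(),
                           scale = c("proportion", "percent"),
                           label = config$algorithm) {
  stopifnot(inherits(data, "ccd_table"), !is.null(data$observed),
            inherits(plan, "cv_plan"))
  scale <- match.arg(scale)
  n <- nrow(data$coded)
  y_all <- if (scale == "proportion") data$observed / 100 else data$observed
  repeat_mse <- numeric(plan$repeats)
  n_divergent <- 0L
  for (r in seq_len(plan$repeats)) {
    folds <- kfold_indices(n, plan$k, plan$seed + r)
    sq_err <- numeric(0)
    for (f in seq_along(folds)) {
      hold <- folds[[f]]
      train_idx <- setdiff(seq_len(n), hold)
      Xtr <- data$coded[train_idx, , drop = FALSE]
      ytr <- y_all[train_idx]
      fold_err <- tryCatch({
        xs <- fit_scaler(Xtr)
        ys <- fit_scaler(matrix(ytr, ncol = 1))
        cfg <- config
        cfg$seed <- config$seed + 97L * r + f
        rec <- bp_train(arch, scaler_apply(xs, Xtr),
                        scaler_apply(ys, matrix(ytr, ncol = 1)), cfg)
        pred <- scaler_invert(ys, bp_forward(rec$weights,
                                             scaler_apply(xs, data$coded[hold, , drop = FALSE])))
        (y_all[hold] - as.numeric(pred))^2
      }, error = function(e) {
        n_divergent <<- n_divergent + 1L
        rep(stats::var(ytr), length(hold))
      })
      sq_err <- c(sq_err, fold_err)
    }
    repeat_mse[r] <- mean(sq_err)
  }
  structure(list(label = label, mean_mse = mean(repeat_mse),
                 repeat_mse = repeat_mse, n_divergent = n_divergent),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean held-out MSE %.5g over %d repeat(s)%s\n",
              x$label, x$mean_mse, length(x$repeat_mse),
              if (x$n_divergent > 0) sprintf(" [%d divergent fold(s)]", x$n_divergent) else ""))
  invisible(x)
}

rank_cv_results <- function(results) results[order(vapply(results, `[[`, 0, "mean_mse"))]

#' Select the training algorithm by repeated k-fold CV
#'
#' Each candidate trainer is cross-validated at a fixed hidden width
#' (default 6, the width used for the trainer comparison) and the candidates
#' are ranked by mean held-out MSE, best first.
#'
#' @param candidates Character vector of trainer labels
#'   (subset of `"gd"`, `"gdm"`, `"gda"`, `"gdx"`, `"lm"`).
#' @param data A `ccd_table` with observed rates.
#' @param plan A `cv_plan`.
#' @param hidden Hidden width used during the comparison (default 6).
#' @param config Base `train_config`; its `algorithm` field is overridden
#'   per candidate.
#' @return List of `cv_result`, sorted ascending by `mean_mse`.
#' @export
select_training_function <- function(candidates = c("gd", "gdm", "gda", "gdx", "lm"),
                                     data, plan = cv_plan(), hidden = 6,
                                     config = train_config()) {
  if (length(candidates) == 0) stop("configuration error: empty candidate list")
  arch <- bp_arch(ncol(data$coded), hidden, 1L)
  results <- lapply(candidates, function(alg) {
    cfg <- config
    cfg$algorithm <- alg
    cross_validate(arch, cfg, data, plan, label = alg)
  })
  rank_cv_results(results)
}

#' Select the hidden-layer width by repeated k-fold CV
#'
#' @param range Integer vector of candidate widths (default `1:15`).
#' @param algorithm Trainer label used for every candidate (default `"gdx"`).
#' @param data A `ccd_table` with observed rates.
#' @param plan A `cv_plan`.
#' @param config Base `train_config`.
#' @return List of `cv_result` (labels are the widths), sorted ascending by
#'   `mean_mse`; the winner is the first element.
#' @export
select_hidden_size <- function(range = 1:15, algorithm = "gdx", data,
                               plan = cv_plan(), config = train_config()) {
  if (length(range) == 0 || any(range < 1))
    stop("configuration error: hidden-width range must be positive integers")
  cfg <- config
  cfg$algorithm <- algorithm
  results <- lapply(as.integer(range), function(h) {
    arch <- bp_arch(ncol(data$coded), h, 1L)
    cross_validate(arch, cfg, data, plan, label = as.character(h))
  })
  rank_cv_results(results)
}

#' Write a CV ranking to CSV
#'
#' Columns: `candidate`, `mean_mse`, `repeat_1..repeat_R`.
#'
#' @param results List of `cv_result` (e.g. from [select_hidden_size()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(results, path) {
  reps <- length(results[[1]]$repeat_mse)
  d <- data.frame(candidate = vapply(results, `[[`, "", "label"),
                  mean_mse = vapply(results, `[[`, 0, "mean_mse"))
  for (r in seq_len(reps))
    d[[paste0("repeat_", r)]] <- vapply(results, function(x) x$repeat_mse[r], 0)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
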