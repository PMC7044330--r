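#' End-to-end pipeline configuration
#'
#' @param plan A `cv_plan` for both selection stages.
#' @param train A base `train_config` (the trainer label is set per stage).
#' @param ga A `ga_config` for the surrogate maximization.
#' @param trainers Candidate trainer labels for stage 1.
#' @param hidden_range Candidate hidden widths for stage 2.
#' @param skip_selection If `TRUE`, skip both CV stages and use `hidden` and
#'   `trainer` directly (the study's final choices by default).
#' @param hidden Hidden width used when selection is skipped (default 3).
#' @param trainer Trainer used when selection is skipped (default `"gdx"`).
#' @param restarts Seeded restarts for the final fit (default 10).
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Optional directory for JSON/CSV artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(plan = cv_plan(), train = train_config(),
                            ga = ga_config(),
                            trainers = c("gd", "gdm", "gda", "gdx", "lm"),
                            hidden_range = 1:15, skip_selection = FALSE,
                            hidden = 3L, trainer = "gdx", restarts = 10L,
                            seed = 1L, out_dir = NULL) {
  stopifnot(restarts >= 1)
  structure(list(plan = plan, train = train, ga = ga, trainers = trainers,
                 hidden_range = hidden_range, skip_selection = skip_selection,
                 hidden = as.integer(hidden), trainer = trainer,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full surrogate-optimization workflow
#'
#' Stages: (1) select the trainer by repeated k-fold CV at hidden width 6;
#' (2) select the hidden width with the winning trainer; (3) train the final
#' surrogate on all rows, best of `restarts` seeded initializations by
#' training MSE; (4) maximize the surrogate over the coded box with the
#' real-coded GA; (5) fit the full-quadratic response-surface baseline and
#' its box maximum; (6) assemble metrics. Fully reproducible from
#' `config$seed`.
#'
#' @param data A `ccd_table` with observed rates (e.g. [load_table1()]).
#' @param config A `pipeline_config`.
#' @return Object of class `run_report`; see Details.
#' @details The report fields: `trainer` (label + CV ranking), `hidden`
#'   (width + CV ranking), `net` (the final `bp_net`), `fit_metrics`
#'   (training R-squared, RMSE on percent and proportion scales), `ga` (the
#'   `ga_result`, plus the decoded best point in actual units), `rsm`
#'   (`quadratic_model`, its R-squared and box maximum), `seeds`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(data, "ccd_table"), !is.null(data$observed),
            inherits(config, "pipeline_config"))
  seeds <- list(cv_trainer = config$seed, cv_hidden = config$seed + 10000L,
                final_train = config$seed + 20000L, ga = config$seed + 30000L)

  trainer_rank <- NULL; hidden_rank <- NULL
  trainer <- config$trainer; hidden <- config$hidden
  if (!config$skip_selection) {
    plan1 <- config$plan; plan1$seed <- seeds$cv_trainer
    trainer_rank <- select_training_function(config$trainers, data, plan1,
                                             hidden = 6, config = config$train)
    trainer <- trainer_rank[[1]]$label
    plan2 <- config$plan; plan2$seed <- seeds$cv_hidden
    hidden_rank <- select_hidden_size(config$hidden_range, trainer, data,
                                      plan2, config = config$train)
    hidden <- as.integer(hidden_rank[[1]]$label)
  }

  cfg <- config$train
  cfg$algorithm <- trainer
  cfg$seed <- seeds$final_train
  net <- fit_bp_surrogate(data, n_hidden = hidden, config = cfg,
                          restarts = config$restarts)

  fitted <- predict(net, data$coded)
  fit_metrics <- list(
    r_squared = r_squared(data$observed, fitted),
    rmse_percent = rmse(data$observed, fitted, scale = "percent"),
    rmse_proportion = rmse(data$observed, fitted, scale = "proportion")
  )

  ga_cfg <- config$ga
  ga_cfg$seed <- seeds$ga
  ga_res <- run_ga(surrogate_fitness(net), ga_cfg)
  ga_actual <- decode_point(ga_res$best_point, data$factors)

  rsm_fit <- fit_full_quadratic(data)
  rsm_max <- maximize_quadratic(rsm_fit, ga_cfg$bounds)

  report <- structure(list(
    trainer = list(label = trainer, ranking = trainer_rank),
    hidden = list(width = hidden, ranking = hidden_rank),
    net = net, fit_metrics = fit_metrics,
    ga = list(result = ga_res, best_coded = ga_res$best_point,
              best_actual = ga_actual, best_fitness = ga_res$best_fitness),
    rsm = list(model = rsm_fit, r_squared = rsm_fit$r_squared,
               maximum = rsm_max),
    seeds = seeds, config = config
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  trainer: %s   hidden width: %d\n", x$trainer$label, x$hidden$width))
  cat(sprintf("  training R^2 %.4f, RMSE %.4f %% (%.4f proportion)\n",
              x$fit_metrics$r_squared, x$fit_metrics$rmse_percent,
              x$fit_metrics$rmse_proportion))
  cat(sprintf("  GA best rate %.2f %% at coded (%s)\n", x$ga$best_fitness,
              paste(signif(x$ga$best_coded, 4), collapse = ", ")))
  cat(sprintf("         actual units: %s\n",
              paste(signif(x$ga$best_actual, 4), collapse = ", ")))
  cat(sprintf("  RSM R^2 %.4f, box maximum %.2f %%\n",
              x$rsm$r_squared, x$rsm$maximum$value))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes `report.json`, the fitted surrogate (`bp_net.json`), the RSM
#' coefficients (`rsm_coefficients.csv`), the GA history
#' (`ga_history.csv`) and, when selection ran, the CV tables.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- list(
    trainer = report$trainer$label,
    hidden_width = report$hidden$width,
    fit_metrics = report$fit_metrics,
    ga = list(best_coded = report$ga$best_coded,
              best_actual = report$ga$best_actual,
              best_fitness = report$ga$best_fitness),
    rsm = list(r_squared = report$rsm$r_squared,
               max_point = report$rsm$maximum$point,
               max_value = report$rsm$maximum$value),
    seeds = report$seeds
  )
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_bp_net(report$net, file.path(dir, "bp_net.json"))
  utils::write.csv(quadratic_coef_table(report$rsm$model),
                   file.path(dir, "rsm_coefficients.csv"),
                   row.names = FALSE, quote = FALSE)
  write_ga_history_csv(report$ga$result, file.path(dir, "ga_history.csv"))
  if (!is.null(report$trainer$ranking))
    write_cv_csv(report$trainer$ranking, file.path(dir, "cv_trainers.csv"))
  if (!is.null(report$hidden$ranking))
    write_cv_csv(report$hidden$ranking, file.path(dir, "cv_hidden.csv"))
  invisible(dir)
}

#' Compare a predicted optimum against wet-lab replicate observations
#'
#' The validation-table layout: replicate listing, replicate mean, and the
#' relative error of the prediction against that mean.
#'
#' @param predicted Predicted rate (%), or a `run_report` whose GA best
#'   fitness is used.
#' @param observed Numeric vector of observed replicate rates (%).
#' @return List with `predicted`, `replicates`, `mean`, `error_pct`.
#' @examples
#' v <- validate_against(91.97, c(90.35, 89.97, 91.26))
#' round(c(v$mean, v$error_pct), 2)  # 90.53 1.59
#' @export
validate_against <- function(predicted, observed) {
  if (inherits(predicted, "run_report")) predicted <- predicted$ga$best_fitness
  if (length(observed) == 0) stop("input error: no observed replicates")
  m <- mean(observed)
  list(predicted = predicted, replicates = observed, mean = m,
       error_pct = relative_error_pct(predicted, m))
}
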