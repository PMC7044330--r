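#' Configuration for the real-coded genetic algorithm
#'
#' Population size 20, crossover probability 0.8 and a 100-generation budget
#' follow the melon study's settings; selection, mutation and elitism are
#' unstated there and default to standard real-coded practice (tournament
#' size 2, per-gene Gaussian mutation, two elites).
#'
#' @param population_size Number of individuals (default 20).
#' @param crossover_prob Probability a child is produced by arithmetic
#'   crossover (default 0.8).
#' @param mutation_prob Per-gene mutation probability (default 0.1).
#' @param mutation_sd Gaussian mutation standard deviation in coded units
#'   (default 0.2).
#' @param elite_count Individuals copied unchanged into the next generation
#'   (default 2; must be < `population_size`).
#' @param selection `"tournament"` (size 2) or `"roulette"`.
#' @param max_generations Number of generations to run (default 100).
#' @param bounds 2-row matrix (`rbind(lower, upper)`) or list of c(lo, hi)
#'   per dimension, in coded units; default the `[-2, 2]^4` design box.
#' @param seed Integer seed; the run is fully reproducible.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L, crossover_prob = 0.8,
                      mutation_prob = 0.1, mutation_sd = 0.2,
                      elite_count = 2L,
                      selection = c("tournament", "roulette"),
                      max_generations = 100L,
                      bounds = matrix(c(-2, 2), 2, 4,
                                      dimnames = list(c("lower", "upper"), NULL)),
                      seed = 1L) {
  selection <- match.arg(selection)
  if (is.list(bounds)) bounds <- vapply(bounds, as.numeric, numeric(2))
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2, all(bounds[1, ] < bounds[2, ]),
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1, mutation_sd >= 0,
            elite_count >= 0, elite_count < population_size,
            population_size >= 2, max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 mutation_sd = mutation_sd, elite_count = as.integer(elite_count),
                 selection = selection,
                 max_generations = as.integer(max_generations),
                 bounds = bounds, seed = as.integer(seed)),
            class = "ga_config")
}

#' Maximize a black-box fitness with a real-coded genetic algorithm
#'
#' Generational loop: evaluate, carry over `elite_count` elites, select
#' parents, apply arithmetic crossover with probability `crossover_prob`
#' (child = `u * p1 + (1 - u) * p2`, blend weight `u` uniform), mutate each
#' gene with probability `mutation_prob` by adding Gaussian noise clipped to
#' the bounds, and replace. With at least one elite the per-generation best
#' fitness is non-decreasing.
#'
#' @param fitness Function mapping a coded vector to a finite scalar
#'   (larger is better).
#' @param config A `ga_config`.
#' @return Object of class `ga_result`: `best_point` (coded), `best_fitness`,
#'   `history` (per-generation best fitness), `generations_run`, `config`.
#' @examples
#' res <- run_ga(function(x) -sum(x^2), ga_config(seed = 7, max_generations = 40))
#' res$best_fitness
#' @export
run_ga <- function(fitness, config = ga_config()) {
  stopifnot(is.function(fitness), inherits(config, "ga_config"))
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  d <- length(lo); N <- config$population_size
  eval_fit <- function(P) {
    f <- apply(P, 1, fitness)
    bad <- which(!is.finite(f))
    if (length(bad))
      stop("fitness-domain error: non-finite fitness at point (",
           paste(signif(P[bad[1], ], 6), collapse = ", "), ")")
    f
  }
  withr::with_seed(config$seed, {
    P <- matrix(stats::runif(N * d, rep(lo, each = N), rep(hi, each = N)), N, d)
    f <- eval_fit(P)
    history <- numeric(config$max_generations)
    for (g in seq_len(config$max_generations)) {
      ord <- order(f, decreasing = TRUE)
      n_children <- N - config$elite_count
      parents_of <- function() {
        if (config$selection == "tournament") {
          i <- sample.int(N, 2); j <- sample.int(N, 2)
          c(if (f[i[1]] >= f[i[2]]) i[1] else i[2],
            if (f[j[1]] >= f[j[2]]) j[1] else j[2])
        } else {
          w <- f - min(f) + 1e-12
          sample.int(N, 2, replace = TRUE, prob = w)
        }
      }
      children <- matrix(0, n_children, d)
      for (c_i in seq_len(n_children)) {
        pr <- parents_of()
        child <- if (stats::runif(1) < config$crossover_prob) {
          u <- stats::runif(1)
          u * P[pr[1], ] + (1 - u) * P[pr[2], ]
        } else P[pr[1], ]
        mut <- stats::runif(d) < config$mutation_prob
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, config$mutation_sd)
        children[c_i, ] <- pmin(pmax(child, lo), hi)
      }
      P_new <- rbind(P[ord[seq_len(config$elite_count)], , drop = FALSE], children)
      f_new <- c(f[ord[seq_len(config$elite_count)]], eval_fit(children))
      P <- P_new; f <- f_new
      history[g] <- max(f)   # with >= 1 elite this sequence is non-decreasing
    }
    best <- which.max(f)
    structure(list(best_point = P[best, ], best_fitness = f[best],
                   history = history,
                   generations_run = config$max_generations, config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.4f at (%s) after %d generations\n",
              x$best_fitness, paste(signif(x$best_point, 4), collapse = ", "),
              x$generations_run))
  invisible(x)
}

#' Wrap a fitted surrogate as a GA fitness function
#'
#' Applies input scaling, the forward pass and inverse output scaling;
#' returns the percent-scale predicted rate at a coded design point.
#'
#' @param net A `bp_net` from [fit_bp_surrogate()].
#' @return Function mapping a coded vector to a predicted rate (%).
#' @export
surrogate_fitness <- function(net) {
  stopifnot(inherits(net, "bp_net"))
  function(x) predict(net, matrix(x, nrow = 1))
}

#' Write a GA fitness history to CSV
#'
#' Columns `generation`, `best_fitness` — the per-generation convergence
#' curve of the search.
#'
#' @param result A `ga_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ga_history_csv <- function(result, path) {
  utils::write.csv(data.frame(generation = seq_along(result$history),
                              best_fitness = result$history),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
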