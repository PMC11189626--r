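MARKOV_STRATEGIES <- c("random", "serial_cw", "serial_ccw", "spatial")

#' Markov-chain strategy model parameters
#'
#' Four strategies — random, serial clockwise, serial counterclockwise,
#' spatial — form the states of a Markov chain over segments: the first
#' segment's strategy is drawn from `initial`, each subsequent segment's
#' from the transition row of the previous strategy, and the selected
#' strategy's stochastic process draws the vestibule. Jointly the
#' parameters form a 5x4 row-stochastic matrix (initial row on top).
#'
#' @param initial Length-4 probability vector (order: random, serial_cw,
#'   serial_ccw, spatial).
#' @param transitions 4x4 row-stochastic matrix, row i = transition
#'   probabilities out of strategy i (same order).
#' @return An object of class `"markov_params"`.
#' @export
markov_params <- function(initial, transitions) {
  initial <- as.numeric(initial)
  transitions <- as.matrix(transitions)
  if (length(initial) != 4L || !all(dim(transitions) == c(4L, 4L)))
    stop("initial must have length 4 and transitions must be 4x4")
  rows <- rbind(initial, transitions)
  if (any(rows < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(rows) - 1) > 1e-9))
    stop("initial and every transition row must sum to 1")
  dimnames(transitions) <- list(MARKOV_STRATEGIES, MARKOV_STRATEGIES)
  names(initial) <- MARKOV_STRATEGIES
  structure(list(initial = initial, transitions = transitions),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat("Markov-chain strategy model\n  initial:\n")
  print(round(x$initial, 3))
  cat("  transitions (rows = from):\n")
  print(round(x$transitions, 3))
  invisible(x)
}

# 5x4 matrix <-> markov_params
params_to_matrix <- function(params) {
  unname(rbind(params$initial, params$transitions))
}

matrix_to_params <- function(mat) {
  markov_params(mat[1L, ], mat[2:5, , drop = FALSE])
}

#' Clamp and renormalize matrix rows onto the probability simplex
#'
#' Negative entries are set to 0 and each row is divided by its sum; a row
#' that is entirely zero after clamping falls back to the uniform row.
#'
#' @param m A numeric matrix.
#' @return A row-stochastic matrix of the same shape.
#' @export
normalize_rows <- function(m) {
  m <- as.matrix(m)
  m[m < 0] <- 0
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    m[zero, ] <- 1 / ncol(m)
    rs[zero] <- 1
  }
  m / rs
}

#' Simulate one trial from the Markov-chain model
#'
#' @param params A [markov_params()].
#' @param start Start vestibule index.
#' @param config A [maze_config()].
#' @param strategy_params A [strategy_params()].
#' @param mouse_id,day,trial Identifiers stored in the trial.
#' @return A [maze_trial()] with per-segment `strategy_labels` from
#'   `c("random", "serial_cw", "serial_ccw", "spatial")`.
#' @export
simulate_markov_trial <- function(params, start, config = maze_config(),
                                  strategy_params = NULL,
                                  mouse_id = "m1", day = 1L, trial = 1L) {
  sp <- strategy_params %||% default_strategy_params()
  eng <- sim_markov_engine(start, params_to_matrix(params), config, sp,
                           want_labels = TRUE)
  len <- eng$lengths[1L]
  maze_trial(mouse_id, day, trial, start,
             visits = if (len > 0L) eng$visits[seq_len(len), 1L] else integer(0),
             strategy_labels = if (len > 0L)
               MARKOV_STRATEGIES[eng$labels[seq_len(len), 1L]],
             truncated = eng$truncated[1L], config = config)
}

#' Simulate a dataset from the Markov-chain model on a start schedule
#'
#' @inheritParams simulate_markov_trial
#' @param schedule Data frame with columns `mouse_id`, `day`, `trial`,
#'   `start`.
#' @param labels Keep per-segment strategy labels (default `TRUE`).
#' @return A [maze_dataset()].
#' @export
simulate_markov_dataset <- function(params, schedule, config = maze_config(),
                                    strategy_params = NULL, labels = TRUE) {
  sp <- strategy_params %||% default_strategy_params()
  stopifnot(nrow(schedule) > 0L)
  eng <- sim_markov_engine(schedule$start, params_to_matrix(params), config,
                           sp, want_labels = labels)
  engine_to_dataset(eng, schedule, MARKOV_STRATEGIES,
                    metadata = list(model = "markov", params = params),
                    config = config)
}

#' Genetic-algorithm mutation operator
#'
#' Adds independent uniform(-`half_range`, `half_range`) noise to every
#' element of a 5x4 probability matrix, then clamps and renormalizes rows.
#'
#' @param individual A 5x4 matrix (initial row + 4 transition rows).
#' @param half_range Half-width of the uniform mutation noise (default 0.1).
#' @return A mutated row-stochastic 5x4 matrix.
#' @export
ga_mutate <- function(individual, half_range = 0.1) {
  noise <- matrix(stats::runif(length(individual), -half_range, half_range),
                  nrow(individual), ncol(individual))
  normalize_rows(individual + noise)
}

#' Genetic-algorithm crossover operator
#'
#' Each row of the offspring is taken from parent `a` or parent `b` with
#' equal probability; rows remain stochastic because both parents' rows
#' are.
#'
#' @param a,b Parent matrices of equal shape.
#' @return An offspring matrix.
#' @export
ga_crossover <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  from_a <- stats::runif(nrow(a)) < 0.5
  out <- b
  out[from_a, ] <- a[from_a, ]
  out
}

#' Fit the Markov-chain strategy model with a genetic algorithm
#'
#' Evolves a population of candidate 5x4 probability matrices toward the
#' target summary distributions. Each generation, every individual is
#' scored by simulating the model on the start schedule and taking the mean
#' squared error of the objective components (by default the per-index
#' segment-size and vestibule distributions for the first `K` segments plus
#' the pooled trial-length and serial-bout distributions). The `elite`
#' lowest-error individuals survive; the rest of the population is refilled
#' by mutating randomly chosen elites on odd generations and by row-wise
#' crossover of elite pairs on even generations. The fitted matrix is the
#' elementwise average of the final elite, renormalized.
#'
#' By default each generation re-simulates with fresh randomness, which
#' avoids overfitting to one noise draw; `freeze_eval = TRUE` evaluates
#' every generation under one frozen simulation seed, making fitness a
#' deterministic function of the individual (and the elite-best error
#' non-increasing).
#'
#' @param target A [maze_dataset()] or precomputed objective list.
#' @param schedule Start schedule used for every candidate simulation.
#' @param population Population size (default 500).
#' @param generations Number of generations (default 500).
#' @param elite Number of survivors per generation (default half the
#'   population).
#' @param mutation_half_range Mutation noise half-width (default 0.1).
#' @param repetitions Independent GA runs (default 1); the best run is
#'   reported and all runs retained.
#' @param components Objective components (see [summary_mse()]).
#' @param K Segment positions for the per-index components (default 10).
#' @param config A [maze_config()].
#' @param strategy_params A [strategy_params()].
#' @param freeze_eval Evaluate all generations under one frozen simulation
#'   seed (default `FALSE`).
#' @param reevaluate_elite Re-score elites every generation (default
#'   `TRUE`); with `FALSE` elites carry cached fitness.
#' @param trial_cap,bout_cap Caps of the trial-length and bout
#'   distributions.
#' @param verbose Progress messages every 25 generations.
#' @return An object of class `"markov_fit"` with elements `best`
#'   ([markov_params()] of the best run), `error_trace` (generations x
#'   repetitions matrix of per-generation best errors), `per_run` (list of
#'   [markov_params()]), `best_mse`, plus the settings.
#' @export
fit_markov <- function(target, schedule, population = 500L,
                       generations = 500L, elite = population %/% 2L,
                       mutation_half_range = 0.1, repetitions = 1L,
                       components = c(PER_INDEX_COMPONENTS, "trial_length",
                                      "serial_bout"),
                       K = 10L, config = maze_config(),
                       strategy_params = NULL, freeze_eval = FALSE,
                       reevaluate_elite = TRUE,
                       trial_cap = 30L, bout_cap = 15L, verbose = FALSE) {
  sp <- strategy_params %||% default_strategy_params()
  population <- as.integer(population)
  generations <- as.integer(generations)
  elite <- as.integer(elite)
  if (population < 2L) stop("population must be at least 2")
  if (elite < 1L || elite >= population)
    stop("elite must lie in 1..population-1")
  target_obj <- as_objective(target, components, trial_cap, bout_cap, K)
  starts <- schedule$start
  evaluate <- function(mat) {
    eng <- sim_markov_engine(starts, mat, config, sp)
    ok <- !eng$truncated
    pool <- pool_from_matrix(eng$starts[ok], eng$lengths[ok],
                             eng$visits[, ok, drop = FALSE], config)
    obj <- objective_from_pool(pool, components, trial_cap, bout_cap, K)
    summary_mse(target_obj, obj, components)
  }
  error_trace <- matrix(NA_real_, generations, repetitions)
  per_run <- vector("list", repetitions)
  run_best_mse <- numeric(repetitions)
  for (run in seq_len(repetitions)) {
    pop <- replicate(population,
                     normalize_rows(matrix(stats::rexp(20L), 5L, 4L)),
                     simplify = FALSE)
    fitness <- rep(NA_real_, population)
    eval_seed <- if (freeze_eval) sample.int(.Machine$integer.max, 1L)
    for (gen in seq_len(generations)) {
      need <- if (reevaluate_elite || gen == 1L) seq_len(population)
              else which(is.na(fitness))
      if (freeze_eval) {
        # fitness must be a deterministic function of the individual alone,
        # so the simulation stream restarts from the frozen seed per
        # evaluation and the GA's own stream is restored afterwards
        saved <- get(".Random.seed", envir = globalenv())
        fitness[need] <- vapply(pop[need], function(mat) {
          set.seed(eval_seed)
          evaluate(mat)
        }, 0)
        assign(".Random.seed", saved, envir = globalenv())
      } else {
        fitness[need] <- vapply(pop[need], evaluate, 0)
      }
      ord <- order(fitness)
      elite_idx <- ord[seq_len(elite)]
      error_trace[gen, run] <- fitness[ord[1L]]
      if (verbose && gen %% 25L == 0L)
        message("run ", run, " gen ", gen, ": best mse ",
                signif(fitness[ord[1L]], 4))
      if (gen == generations) {
        avg <- Reduce(`+`, pop[elite_idx]) / elite
        per_run[[run]] <- matrix_to_params(normalize_rows(avg))
        run_best_mse[run] <- fitness[ord[1L]]
        break
      }
      n_new <- population - elite
      offspring <- if (gen %% 2L == 1L) {
        parents <- sample(elite_idx, n_new, replace = TRUE)
        lapply(pop[parents], ga_mutate, half_range = mutation_half_range)
      } else {
        pa <- sample(elite_idx, n_new, replace = TRUE)
        pb <- sample(elite_idx, n_new, replace = TRUE)
        lapply(seq_len(n_new), function(i)
          ga_crossover(pop[[pa[i]]], pop[[pb[i]]]))
      }
      pop <- c(pop[elite_idx], offspring)
      fitness <- c(fitness[elite_idx], rep(NA_real_, n_new))
    }
  }
  best_run <- which.min(run_best_mse)
  structure(
    list(best = per_run[[best_run]], per_run = per_run,
         error_trace = error_trace, best_mse = run_best_mse[best_run],
         run_best_mse = run_best_mse, population = population,
         generations = generations, elite = elite,
         components = components, K = K, freeze_eval = freeze_eval,
         n_trials = length(starts), call = match.call()),
    class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf(paste0("Markov-chain model, genetic-algorithm fit ",
                     "(pop %d, %d generations, %d run(s))\n"),
              x$population, x$generations, ncol(x$error_trace)))
  cat("  best final mse:", signif(x$best_mse, 5), "\n")
  print(x$best)
  invisible(x)
}

#' @export
coef.markov_fit <- function(object, ...) {
  m <- params_to_matrix(object$best)
  dimnames(m) <- list(c("initial", MARKOV_STRATEGIES), MARKOV_STRATEGIES)
  m
}

#' @export
summary.markov_fit <- function(object, ...) {
  cat("Call: ")
  print(object$call)
  print(object)
  if (length(object$per_run) > 1L) {
    mats <- lapply(object$per_run, params_to_matrix)
    spread <- apply(simplify2array(mats), c(1, 2), stats::sd)
    dimnames(spread) <- dimnames(coef(object))
    cat("\nElementwise sd across runs:\n")
    print(round(spread, 3))
  }
  invisible(object)
}

#' Plot the genetic-algorithm error traces
#'
#' Best mean squared error per generation, one line per repetition.
#'
#' @param x A `"markov_fit"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.markov_fit <- function(x, ...) {
  graphics::matplot(x$error_trace, type = "l", lty = 1,
                    xlab = "generation", ylab = "best m.s.e.",
                    main = "Genetic algorithm convergence", ...)
  invisible(x)
}

#' Simulate datasets from a fitted Markov-chain model
#'
#' @param object A `"markov_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional seed passed to [set.seed()].
#' @param schedule Start schedule (required).
#' @param ... Passed to [simulate_markov_dataset()].
#' @return A [maze_dataset()] if `nsim = 1`, else a list of them.
#' @export
simulate.markov_fit <- function(object, nsim = 1, seed = NULL, schedule,
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_markov_dataset(object$best, schedule, ...))
  if (nsim == 1) out[[1L]] else out
}
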