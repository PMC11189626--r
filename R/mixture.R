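#' Mixture-model parameters
#'
#' The mixture model alternates two steps: draw a strategy (random, serial,
#' spatial) according to percentage weights, then let that strategy's
#' stochastic process generate the next `n_persist` segments; the trial ends
#' as soon as the goal is visited, mid-block or not. `n_persist` is the
#' strategy persistence N: the number of consecutive segments produced under
#' one strategy before the strategy is redrawn.
#'
#' @param p_random,p_serial,p_spatial Strategy percentages, summing to 100.
#' @param n_persist Persistence N in segments (default 6).
#' @return An object of class `"mixture_params"`.
#' @export
mixture_params <- function(p_random, p_serial, p_spatial, n_persist = 6L) {
  p <- as.numeric(c(p_random, p_serial, p_spatial))
  if (any(p < 0)) stop("strategy percentages must be non-negative")
  if (abs(sum(p) - 100) > 1e-6) stop("strategy percentages must sum to 100")
  n_persist <- as.integer(n_persist)
  if (n_persist < 1L) stop("n_persist must be >= 1")
  structure(list(p_random = p[1L], p_serial = p[2L], p_spatial = p[3L],
                 n_persist = n_persist),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Mixture: random %.1f%% / serial %.1f%% / spatial %.1f%%, N = %d\n",
              x$p_random, x$p_serial, x$p_spatial, x$n_persist))
  invisible(x)
}

#' Simulate one trial from the mixture model
#'
#' @param params A [mixture_params()].
#' @param start Start vestibule index.
#' @param config A [maze_config()].
#' @param strategy_params A [strategy_params()].
#' @param mouse_id,day,trial Identifiers stored in the trial.
#' @return A [maze_trial()] with per-segment `strategy_labels` in
#'   `c("random", "serial", "spatial")`.
#' @examples
#' set.seed(42)
#' simulate_mixture_trial(mixture_params(30, 30, 40), start = 12)
#' @export
simulate_mixture_trial <- function(params, start, config = maze_config(),
                                   strategy_params = NULL,
                                   mouse_id = "m1", day = 1L, trial = 1L) {
  sp <- strategy_params %||% default_strategy_params()
  eng <- sim_mixture_engine(start, c(params$p_random, params$p_serial,
                                     params$p_spatial),
                            params$n_persist, config, sp, want_labels = TRUE)
  len <- eng$lengths[1L]
  maze_trial(mouse_id, day, trial, start,
             visits = if (len > 0L) eng$visits[seq_len(len), 1L] else integer(0),
             strategy_labels = if (len > 0L)
               c("random", "serial", "spatial")[eng$labels[seq_len(len), 1L]],
             truncated = eng$truncated[1L], config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a dataset from the mixture model on a start schedule
#'
#' One trial per schedule row, all sharing the same mixture parameters (the
#' estimation procedure simulates each day with that day's candidate
#' parameters and that day's experimental start positions).
#'
#' @param params A [mixture_params()].
#' @param schedule Data frame with columns `mouse_id`, `day`, `trial`,
#'   `start`.
#' @inheritParams simulate_mixture_trial
#' @param labels Keep per-segment strategy labels (default `TRUE`).
#' @return A [maze_dataset()].
#' @export
simulate_mixture_dataset <- function(params, schedule,
                                     config = maze_config(),
                                     strategy_params = NULL,
                                     labels = TRUE) {
  sp <- strategy_params %||% default_strategy_params()
  stopifnot(nrow(schedule) > 0L)
  eng <- sim_mixture_engine(schedule$start,
                            c(params$p_random, params$p_serial,
                              params$p_spatial),
                            params$n_persist, config, sp, want_labels = labels)
  engine_to_dataset(eng, schedule, c("random", "serial", "spatial"),
                    metadata = list(model = "mixture", params = params),
                    config = config)
}

#' Simplex grid of strategy-percentage triples
#'
#' All non-negative triples (p_random, p_serial, p_spatial) summing to 100
#' in steps of `increment`.
#'
#' @param increment Grid step in percent; must divide 100.
#' @return A data frame with columns `p_random`, `p_serial`, `p_spatial`.
#' @export
mixture_grid <- function(increment = 2) {
  if (increment <= 0 || 100 %% increment != 0)
    stop("increment must be a positive divisor of 100")
  pr <- seq(0, 100, by = increment)
  rows <- lapply(pr, function(a) {
    b <- seq(0, 100 - a, by = increment)
    data.frame(p_random = a, p_serial = b, p_spatial = 100 - a - b)
  })
  do.call(rbind, rows)
}

#' Fit the mixture model by exhaustive grid search
#'
#' For every strategy-percentage triple on the simplex grid (and every
#' persistence value in `n_persist`), simulates the model on the given start
#' schedule, summarizes the simulated sequences, and scores the mean
#' squared error against the target distributions. Simulation noise is
#' reduced by repeating each evaluation `repetitions` times; by default the
#' error surfaces are averaged across repetitions before the arg-minimum is
#' taken (`average = "surface"`); `average = "argmin"` instead averages the
#' per-repetition optimal triples. Ties on the averaged surface break
#' toward larger `p_spatial`, then larger `p_serial`.
#'
#' When `n_persist` has length > 1 the whole grid search is repeated per N
#' (the N scan): `error_by_n` records the minimal averaged error per N and
#' the fit is reported at the best N.
#'
#' @param target A [maze_dataset()] of observed (or synthetic) trials, or a
#'   precomputed objective list from [summarize_objective()].
#' @param schedule Start schedule (see [simulate_mixture_dataset()]) used
#'   for every candidate simulation, mirroring the experimental mice,
#'   trials, and start positions.
#' @param increment Grid step in percent (default 2).
#' @param n_persist Persistence value(s) to evaluate (default 6; a vector
#'   triggers the N scan).
#' @param repetitions Independent simulations averaged per grid point
#'   (default 10).
#' @param components Summary components entering the error (default: the
#'   four pooled distributions).
#' @param config A [maze_config()].
#' @param strategy_params A [strategy_params()].
#' @param average `"surface"` or `"argmin"` (see Details).
#' @param trial_cap,bout_cap Caps of the trial-length and bout
#'   distributions.
#' @param verbose Print progress per N.
#' @return An object of class `"mixture_fit"` with elements `best`
#'   ([mixture_params()]), `surface` (data frame `n_persist, p_random,
#'   p_serial, p_spatial, mse`), `error_by_n` (named vector),
#'   `repetitions`, `increment`, `components`.
#' @seealso [scan_n()] for the N-scan shorthand.
#' @export
fit_mixture <- function(target, schedule, increment = 2, n_persist = 6L,
                        repetitions = 10L,
                        components = SUMMARY_COMPONENTS,
                        config = maze_config(), strategy_params = NULL,
                        average = c("surface", "argmin"),
                        trial_cap = 30L, bout_cap = 15L, verbose = FALSE) {
  average <- match.arg(average)
  sp <- strategy_params %||% default_strategy_params()
  n_persist <- as.integer(n_persist)
  if (!length(n_persist)) stop("n_persist must contain at least one value")
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  target_obj <- as_objective(target, components, trial_cap, bout_cap)
  grid <- mixture_grid(increment)
  ng <- nrow(grid)
  starts <- schedule$start
  surfaces <- vector("list", length(n_persist))
  argmins <- vector("list", length(n_persist))
  for (j in seq_along(n_persist)) {
    N <- n_persist[j]
    errs <- matrix(NA_real_, ng, repetitions)
    for (rep in seq_len(repetitions)) {
      for (gidx in seq_len(ng)) {
        eng <- sim_mixture_engine(starts,
                                  c(grid$p_random[gidx], grid$p_serial[gidx],
                                    grid$p_spatial[gidx]),
                                  N, config, sp)
        pool <- pool_from_matrix(eng$starts[!eng$truncated],
                                 eng$lengths[!eng$truncated],
                                 eng$visits[, !eng$truncated, drop = FALSE],
                                 config)
        obj <- objective_from_pool(pool, components, trial_cap, bout_cap)
        errs[gidx, rep] <- summary_mse(target_obj, obj, components)
      }
    }
    surfaces[[j]] <- rowMeans(errs)
    argmins[[j]] <- apply(errs, 2L, function(e) best_grid_row(grid, e))
    if (verbose)
      message("N = ", N, ": min averaged mse = ",
              signif(min(surfaces[[j]]), 4))
  }
  error_by_n <- vapply(surfaces, min, 0)
  names(error_by_n) <- n_persist
  j_best <- which.min(error_by_n)
  N_best <- n_persist[j_best]
  if (average == "surface") {
    i_best <- best_grid_row(grid, surfaces[[j_best]])
    best_triple <- as.numeric(grid[i_best, ])
  } else {
    rows <- grid[argmins[[j_best]], , drop = FALSE]
    best_triple <- colMeans(rows)
    best_triple <- 100 * best_triple / sum(best_triple)
  }
  surface_df <- do.call(rbind, lapply(seq_along(n_persist), function(j)
    data.frame(n_persist = n_persist[j], grid, mse = surfaces[[j]])))
  structure(
    list(best = mixture_params(best_triple[1L], best_triple[2L],
                               best_triple[3L], N_best),
         surface = surface_df, error_by_n = error_by_n,
         repetitions = repetitions, increment = increment,
         components = components, average = average,
         n_trials = length(starts), call = match.call()),
    class = "mixture_fit")
}

# index of the minimal-mse grid row; ties resolve toward larger p_spatial
# then larger p_serial
best_grid_row <- function(grid, mse) {
  order(mse, -grid$p_spatial, -grid$p_serial)[1L]
}

as_objective <- function(target, components, trial_cap, bout_cap, K = 10L) {
  if (inherits(target, "maze_dataset"))
    return(summarize_objective(target, components, trial_cap, bout_cap, K,
                               quiet = FALSE))
  target <- unclass(target)
  if (!all(components %in% names(target)))
    stop("target lacks component(s): ",
         paste(setdiff(components, names(target)), collapse = ", "))
  target[components]
}

#' Scan the strategy persistence N
#'
#' Runs [fit_mixture()] over a range of persistence values and reports the
#' per-N minimal averaged error and the best N; equivalent to calling
#' `fit_mixture(..., n_persist = n_range)`.
#'
#' @inheritParams fit_mixture
#' @param n_range Integer vector of N values (default 1:15).
#' @return A `"mixture_fit"` (see [fit_mixture()]); its `error_by_n` element
#'   is the scan profile and `best$n_persist` the selected N.
#' @export
scan_n <- function(target, schedule, n_range = 1:15, increment = 2,
                   repetitions = 10L, ...) {
  fit_mixture(target, schedule, increment = increment, n_persist = n_range,
              repetitions = repetitions, ...)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Mixture-model grid-search fit\n")
  cat(sprintf("  grid increment %s%%, %d repetition(s), %d simulated trials/evaluation\n",
              format(x$increment), x$repetitions, x$n_trials))
  print(x$best)
  cat("  minimal averaged mse:", signif(min(x$error_by_n), 5), "\n")
  if (length(x$error_by_n) > 1L)
    cat("  N scanned:", paste(names(x$error_by_n), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  cat("Call: ")
  print(object$call)
  print(object)
  srt <- object$surface[order(object$surface$mse), ]
  cat("\nTop 5 grid points:\n")
  print(utils::head(srt, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  c(p_random = object$best$p_random, p_serial = object$best$p_serial,
    p_spatial = object$best$p_spatial, n_persist = object$best$n_persist)
}

#' Plot a mixture fit: error surface and N profile
#'
#' Draws the averaged error over the (p_random, p_serial) simplex for the
#' best N (filled image, p_spatial implied by the complement) and, when the
#' fit scanned several N, the error-by-N profile.
#'
#' @param x A `"mixture_fit"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.mixture_fit <- function(x, ...) {
  scan <- length(x$error_by_n) > 1L
  if (scan) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  N <- x$best$n_persist
  s <- x$surface[x$surface$n_persist == N, ]
  pr <- sort(unique(s$p_random))
  ps <- sort(unique(s$p_serial))
  z <- matrix(NA_real_, length(pr), length(ps))
  z[cbind(match(s$p_random, pr), match(s$p_serial, ps))] <- s$mse
  graphics::image(pr, ps, z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "P_random (%)", ylab = "P_serial (%)",
                  main = sprintf("m.s.e. surface (N = %d)", N), ...)
  graphics::points(x$best$p_random, x$best$p_serial, pch = 4, col = "red",
                   lwd = 2)
  if (scan) {
    graphics::plot(as.integer(names(x$error_by_n)), x$error_by_n,
                   type = "b", xlab = "N (segments)",
                   ylab = "minimal averaged m.s.e.", main = "N scan")
    graphics::abline(v = N, lty = 2)
  }
  invisible(x)
}

#' Simulate datasets from a fitted mixture model
#'
#' @param object A `"mixture_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional seed passed to [set.seed()].
#' @param schedule Start schedule (required).
#' @param ... Passed to [simulate_mixture_dataset()].
#' @return A [maze_dataset()] if `nsim = 1`, else a list of them.
#' @export
simulate.mixture_fit <- function(object, nsim = 1, seed = NULL,
                                 schedule, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_mixture_dataset(object$best, schedule, ...))
  if (nsim == 1) out[[1L]] else out
}
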