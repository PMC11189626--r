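#' Spatial strategy parameters
#'
#' The spatial (goal-directed) process draws the next vestibule from a
#' distribution that decays exponentially with door distance to the goal,
#' `w(v) = exp(-d(v, goal)/tau)`: two symmetric negative exponentials on the
#' circle. Larger `tau` flattens the goal bias.
#'
#' @param tau Decay rate in door-intervals (default 2).
#' @return An object of class `"spatial_params"`.
#' @export
spatial_params <- function(tau = 2) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  structure(list(tau = tau), class = "spatial_params")
}

#' Serial strategy parameters
#'
#' The serial process steps a small noisy number of door-intervals from the
#' current vestibule, emulating consecutive-hole visiting. Steps are
#' `round(center + sd * z)` with `z` standard normal, with distinct center
#' and spread for the clockwise and counterclockwise directions, and (in the
#' unified two-direction process) a sign bias `p_cw` toward clockwise.
#'
#' @param center_cw Clockwise step offset (default 1.2).
#' @param center_ccw Counterclockwise step offset (default -2).
#' @param sd_cw Clockwise step standard deviation (default 1.2).
#' @param sd_ccw Counterclockwise step standard deviation (default 1.5).
#' @param p_cw Probability that the unified process draws a clockwise
#'   (positive) step (default 0.8).
#' @return An object of class `"serial_params"`.
#' @export
serial_params <- function(center_cw = 1.2, center_ccw = -2,
                          sd_cw = 1.2, sd_ccw = 1.5, p_cw = 0.8) {
  if (sd_cw <= 0 || sd_ccw <= 0) stop("step standard deviations must be positive")
  if (p_cw < 0 || p_cw > 1) stop("p_cw must lie in [0, 1]")
  structure(list(center_cw = center_cw, center_ccw = center_ccw,
                 sd_cw = sd_cw, sd_ccw = sd_ccw, p_cw = p_cw),
            class = "serial_params")
}

#' Bundle of all stochastic-process parameters
#'
#' @param spatial A [spatial_params()].
#' @param serial A [serial_params()].
#' @param max_steps_per_trial Step guard per simulated trial (default 1000):
#'   a trial that has not reached the goal after this many segments is
#'   flagged truncated.
#' @return An object of class `"strategy_params"`.
#' @export
strategy_params <- function(spatial = spatial_params(),
                            serial = serial_params(),
                            max_steps_per_trial = 1000L) {
  max_steps_per_trial <- as.integer(max_steps_per_trial)
  if (max_steps_per_trial < 1L) stop("max_steps_per_trial must be >= 1")
  structure(list(spatial = spatial, serial = serial,
                 max_steps_per_trial = max_steps_per_trial),
            class = "strategy_params")
}

# default parameter bundle usable where a function argument shadows the
# constructor's name
default_strategy_params <- function() strategy_params()

#' Random-strategy draw
#'
#' Draws the next vestibule uniformly over all vestibules other than the
#' current one (a repeat would make a zero-size segment, which the segment
#' algebra excludes). Vectorized over `current`; uses R's global RNG.
#'
#' @param current Current vestibule index (vector allowed).
#' @param config A [maze_config()].
#' @return Integer vector of next vestibules, same length as `current`.
#' @export
draw_random_step <- function(current, config = maze_config()) {
  current <- check_vestibule(current, config)
  n <- config$n_vestibules
  offs <- 1L + as.integer(floor(stats::runif(length(current)) * (n - 1L)))
  (current + offs) %% n
}

#' Exponential goal-distance weights of the spatial process
#'
#' @param config A [maze_config()].
#' @param params A [spatial_params()].
#' @return Numeric vector of length `n_vestibules`: `exp(-d(v, goal)/tau)`
#'   for v = 0..n-1 (unnormalized; maximal, equal to 1, at the goal).
#' @export
spatial_weights <- function(config = maze_config(), params = spatial_params()) {
  v <- seq_len(config$n_vestibules) - 1L
  exp(-circular_distance(v, config$goal_index, config) / params$tau)
}

#' Exact next-vestibule probabilities of the spatial process
#'
#' The spatial draw conditions on not repeating the current vestibule, so
#' its effective distribution is the exponential weight vector with the
#' current vestibule removed, renormalized.
#'
#' @param current Current vestibule index (scalar).
#' @inheritParams spatial_weights
#' @return Numeric vector of length `n_vestibules`; entry `current + 1` is 0.
#' @export
spatial_step_probs <- function(current, config = maze_config(),
                               params = spatial_params()) {
  current <- check_vestibule(current, config)
  w <- spatial_weights(config, params)
  w[current + 1L] <- 0
  w / sum(w)
}

#' Spatial-strategy draw
#'
#' Categorical draw over vestibules with probabilities proportional to the
#' exponential goal-distance weights, redrawn while the current vestibule is
#' selected. Vectorized over `current`.
#'
#' @inheritParams draw_random_step
#' @param params A [spatial_params()].
#' @return Integer vector of next vestibules.
#' @export
draw_spatial_step <- function(current, config = maze_config(),
                              params = spatial_params()) {
  current <- check_vestibule(current, config)
  n <- config$n_vestibules
  w <- spatial_weights(config, params)
  nxt <- sample.int(n, length(current), replace = TRUE, prob = w) - 1L
  repeat {
    clash <- which(nxt == current)
    if (!length(clash)) break
    nxt[clash] <- sample.int(n, length(clash), replace = TRUE, prob = w) - 1L
  }
  nxt
}

#' Serial-strategy draw
#'
#' Steps the current vestibule by a stochastic signed number of
#' door-intervals. In `"unified"` mode the step sign is drawn first
#' (clockwise with probability `p_cw`); in `"cw"`/`"ccw"` mode the direction
#' is fixed. The step magnitude is `round(center + sd * z)` for the chosen
#' direction, redrawn until it is nonzero and its sign matches the
#' direction. The whole draw is redone in the (practically unreachable)
#' event that the step wraps exactly onto the current vestibule.
#'
#' @inheritParams draw_random_step
#' @param params A [serial_params()].
#' @param direction `"unified"`, `"cw"`, or `"ccw"`.
#' @return A list with integer vectors `vestibule` (next vestibule) and
#'   `step` (the realized signed step), each the length of `current`.
#' @export
draw_serial_step <- function(current, config = maze_config(),
                             params = serial_params(),
                             direction = c("unified", "cw", "ccw")) {
  direction <- match.arg(direction)
  current <- check_vestibule(current, config)
  n <- config$n_vestibules
  k <- length(current)
  nxt <- integer(k)
  step <- integer(k)
  todo <- seq_len(k)
  while (length(todo)) {
    sgn <- switch(direction,
      unified = ifelse(stats::runif(length(todo)) < params$p_cw, 1L, -1L),
      cw = rep(1L, length(todo)),
      ccw = rep(-1L, length(todo)))
    s <- draw_serial_magnitude(sgn, params)
    nxt[todo] <- (current[todo] + s) %% n
    step[todo] <- s
    todo <- todo[nxt[todo] == current[todo]]
  }
  list(vestibule = nxt, step = step)
}

# round(center + sd*z) per element, resampled until nonzero with the
# requested sign; sgn is +1/-1 per element
draw_serial_magnitude <- function(sgn, params) {
  k <- length(sgn)
  ctr <- ifelse(sgn > 0L, params$center_cw, params$center_ccw)
  sdv <- ifelse(sgn > 0L, params$sd_cw, params$sd_ccw)
  s <- integer(k)
  todo <- seq_len(k)
  while (length(todo)) {
    cand <- as.integer(round(ctr[todo] + sdv[todo] * stats::rnorm(length(todo))))
    ok <- cand != 0L & sign(cand) == sgn[todo]
    s[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  s
}

#' Run one stochastic process until the goal is reached
#'
#' Applies the chosen strategy's draw repeatedly from `start` until the goal
#' vestibule is visited, producing a complete [maze_trial()]. If the goal is
#' not reached within `params$max_steps_per_trial` segments the trial is
#' flagged truncated (or an error is raised in strict mode).
#'
#' @param process One of `"random"`, `"spatial"`, `"serial"` (unified),
#'   `"serial_cw"`, `"serial_ccw"`.
#' @param start Start vestibule index. If equal to the goal the trial is the
#'   degenerate zero-segment trial.
#' @param config A [maze_config()].
#' @param params A [strategy_params()].
#' @param mouse_id,day,trial Identifiers stored in the trial.
#' @param strict If `TRUE`, exceeding the step guard is an error.
#' @return A [maze_trial()] whose `strategy_labels` repeat `process`.
#' @examples
#' set.seed(1)
#' run_process_until_goal("spatial", start = 12)
#' @export
run_process_until_goal <- function(process = c("random", "spatial", "serial",
                                               "serial_cw", "serial_ccw"),
                                   start, config = maze_config(),
                                   params = strategy_params(),
                                   mouse_id = "m1", day = 1L, trial = 1L,
                                   strict = FALSE) {
  process <- match.arg(process)
  start <- check_vestibule(start, config, "start")
  goal <- config$goal_index
  draw <- switch(process,
    random = function(cur) draw_random_step(cur, config),
    spatial = function(cur) draw_spatial_step(cur, config, params$spatial),
    serial = function(cur)
      draw_serial_step(cur, config, params$serial, "unified")$vestibule,
    serial_cw = function(cur)
      draw_serial_step(cur, config, params$serial, "cw")$vestibule,
    serial_ccw = function(cur)
      draw_serial_step(cur, config, params$serial, "ccw")$vestibule)
  visits <- integer(0)
  cur <- start
  truncated <- FALSE
  while (cur != goal) {
    if (length(visits) >= params$max_steps_per_trial) {
      if (strict) stop("step guard exceeded before reaching the goal")
      truncated <- TRUE
      break
    }
    cur <- draw(cur)
    visits <- c(visits, cur)
  }
  maze_trial(mouse_id, day, trial, start, visits,
             strategy_labels = rep(process, length(visits)),
             truncated = truncated, config = config)
}
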