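#' Synthetic experiment plan
#'
#' Describes a full synthetic acquisition experiment mirroring the study
#' design this package models: 19 mice (10 male, 9 female), 10 trials per
#' day over 19 days, starts drawn at least `min_start_distance`
#' door-intervals from the goal, with the same per-day start sequence for
#' all mice. `params` gives the generating model per day: a single
#' [mixture_params()] or [markov_params()] applied to every day, or a list
#' with one element per day.
#'
#' @param n_mice Number of mice (default 19).
#' @param trials_per_day Trials per session (default 10).
#' @param days Number of sessions (default 19).
#' @param min_start_distance Minimal door distance of a start from the goal
#'   (default 2).
#' @param params Generating parameters (see above). Defaults to a mixture
#'   with the early-acquisition strategy weights 58.2/28.4/13.4
#'   (random/serial/spatial) and persistence 6.
#' @param sex Per-mouse group labels; defaults to 10 male + 9 female when
#'   `n_mice` is 19, otherwise unlabelled.
#' @return An object of class `"experiment_plan"`.
#' @export
experiment_plan <- function(n_mice = 19L, trials_per_day = 10L, days = 19L,
                            min_start_distance = 2L,
                            params = mixture_params(58.2, 28.4, 13.4, 6L),
                            sex = NULL) {
  n_mice <- as.integer(n_mice)
  trials_per_day <- as.integer(trials_per_day)
  days <- as.integer(days)
  min_start_distance <- as.integer(min_start_distance)
  if (min(n_mice, trials_per_day, days) < 1L)
    stop("n_mice, trials_per_day and days must all be >= 1")
  if (min_start_distance < 1L) stop("min_start_distance must be >= 1")
  if (is.list(params) && !inherits(params, c("mixture_params",
                                             "markov_params"))) {
    if (length(params) != days)
      stop("per-day params list must have one element per day")
  }
  if (is.null(sex) && n_mice == 19L)
    sex <- rep(c("male", "female"), c(10L, 9L))
  if (!is.null(sex) && length(sex) != n_mice)
    stop("sex must have one label per mouse")
  structure(list(n_mice = n_mice, trials_per_day = trials_per_day,
                 days = days, min_start_distance = min_start_distance,
                 params = params, sex = sex),
            class = "experiment_plan")
}

day_params <- function(plan, day) {
  if (inherits(plan$params, c("mixture_params", "markov_params")))
    plan$params
  else plan$params[[day]]
}

#' Random start schedule shared across mice
#'
#' For each day, draws `trials_per_day` start vestibules uniformly among
#' vestibules at least `min_start_distance` door-intervals from the goal,
#' and replicates that per-day sequence for every mouse (the apparatus uses
#' one start sequence per session for all animals).
#'
#' @param plan An [experiment_plan()].
#' @param config A [maze_config()].
#' @return A data frame with columns `mouse_id, day, trial, start`, ordered
#'   by day, mouse, trial; `n_mice * days * trials_per_day` rows.
#' @export
make_start_schedule <- function(plan, config = maze_config()) {
  v <- seq_len(config$n_vestibules) - 1L
  allowed <- v[circular_distance(v, config$goal_index, config) >=
                 plan$min_start_distance]
  if (!length(allowed))
    stop("min_start_distance excludes every vestibule")
  mice <- sprintf("m%02d", seq_len(plan$n_mice))
  rows <- lapply(seq_len(plan$days), function(d) {
    day_starts <- allowed[sample.int(length(allowed), plan$trials_per_day,
                                     replace = TRUE)]
    data.frame(mouse_id = rep(mice, each = plan$trials_per_day),
               day = d,
               trial = rep(seq_len(plan$trials_per_day), plan$n_mice),
               start = rep(day_starts, plan$n_mice),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a ground-truth-labelled synthetic dataset
#'
#' Simulates every scheduled trial with its day's generating parameters
#' (mixture or Markov model), keeping the generating strategy label of each
#' segment. Errors out if more than `max_truncated_frac` of trials hit the
#' step guard, which indicates a misconfigured guard rather than ordinary
#' stochastic behaviour.
#'
#' @param plan An [experiment_plan()].
#' @param config A [maze_config()].
#' @param strategy_params A [strategy_params()].
#' @param schedule Optional precomputed start schedule (defaults to
#'   [make_start_schedule()], consuming RNG state).
#' @param max_truncated_frac Maximal tolerated truncation rate (default
#'   0.01).
#' @return A [maze_dataset()] with ground-truth `strategy_labels`; metadata
#'   records the plan and per-mouse sex labels.
#' @examples
#' set.seed(7)
#' plan <- experiment_plan(n_mice = 2, days = 1)
#' generate_dataset(plan)
#' @export
generate_dataset <- function(plan, config = maze_config(),
                             strategy_params = NULL, schedule = NULL,
                             max_truncated_frac = 0.01) {
  sp <- strategy_params %||% default_strategy_params()
  if (is.null(schedule)) schedule <- make_start_schedule(plan, config)
  parts <- lapply(seq_len(plan$days), function(d) {
    sub <- schedule[schedule$day == d, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    p <- day_params(plan, d)
    if (inherits(p, "mixture_params"))
      simulate_mixture_dataset(p, sub, config, sp)
    else
      simulate_markov_dataset(p, sub, config, sp)
  })
  parts <- parts[!vapply(parts, is.null, FALSE)]
  ds <- new_maze_dataset(
    unlist(lapply(parts, `[[`, "mouse_id")),
    unlist(lapply(parts, `[[`, "day")),
    unlist(lapply(parts, `[[`, "trial")),
    unlist(lapply(parts, `[[`, "start")),
    do.call(c, lapply(parts, `[[`, "visits")),
    do.call(c, lapply(parts, `[[`, "strategy_labels")),
    unlist(lapply(parts, `[[`, "truncated")),
    metadata = list(plan = plan,
                    sex = if (!is.null(plan$sex))
                      stats::setNames(plan$sex,
                                      sprintf("m%02d", seq_len(plan$n_mice)))),
    config = config)
  frac <- mean(ds$truncated)
  if (frac > max_truncated_frac)
    stop(sprintf("%.1f%% of trials truncated: raise max_steps_per_trial",
                 100 * frac))
  ds
}

#' Synthesize an xy trajectory realizing a visit sequence
#'
#' Builds a piecewise trajectory that reproduces a trial's vestibule
#' sequence when fed through [detect_vestibule_visits()]: a radial
#' excursion `excursion_cm` beyond the visit-radius threshold at each
#' visited vestibule's sector center, connected by arc travel at
#' `arc_frac * visit_radius_cm` in the direction of the signed segment.
#' The path is resampled at the configured sampling rate for constant
#' speed and optionally jittered with isotropic Gaussian noise small
#' enough to preserve threshold crossings. A fixture generator for
#' segmentation tests, not a biomechanical model of rodent movement.
#'
#' @param trial A complete [maze_trial()].
#' @param config A [maze_config()].
#' @param speed_cm_s Travel speed along the path (default 20).
#' @param excursion_cm Depth of the radial excursion beyond the threshold
#'   (default 2).
#' @param arc_frac Arc travel radius as a fraction of the visit radius
#'   (default 0.9).
#' @param jitter_sd Isotropic positional noise SD in cm (default 0.5).
#' @return A data frame with columns `mouse_id, day, trial, t, x, y`
#'   sampled at `config$sample_rate_hz`.
#' @export
synthesize_xy_trajectory <- function(trial, config = maze_config(),
                                     speed_cm_s = 20, excursion_cm = 2,
                                     arc_frac = 0.9, jitter_sd = 0.5) {
  sector <- 2 * pi / config$n_vestibules
  ang <- function(v) -v * sector  # indices increase clockwise
  r_out <- config$visit_radius_cm + excursion_cm
  r_arc <- arc_frac * config$visit_radius_cm
  seg <- trial_segments(trial, config)
  # dense waypoint polyline: out at start, then per segment in-arc-out
  px <- r_out * cos(ang(trial$start))
  py <- r_out * sin(ang(trial$start))
  cur_ang <- ang(trial$start)
  for (i in seq_along(seg)) {
    new_ang <- cur_ang - seg[i] * sector
    n_arc <- max(2L, ceiling(abs(seg[i]) * sector / (pi / 180)))
    arc <- seq(cur_ang, new_ang, length.out = n_arc)
    px <- c(px, r_arc * cos(cur_ang), r_arc * cos(arc),
            r_out * cos(new_ang))
    py <- c(py, r_arc * sin(cur_ang), r_arc * sin(arc),
            r_out * sin(new_ang))
    cur_ang <- new_ang
  }
  d <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  step <- speed_cm_s / config$sample_rate_hz
  s <- seq(0, d[length(d)], by = step)
  x <- stats::approx(d, px, xout = s, ties = "ordered")$y
  y <- stats::approx(d, py, xout = s, ties = "ordered")$y
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, jitter_sd)
    y <- y + stats::rnorm(length(y), 0, jitter_sd)
  }
  data.frame(mouse_id = trial$mouse_id, day = trial$day, trial = trial$trial,
             t = (seq_along(x) - 1L) / config$sample_rate_hz, x = x, y = y,
             stringsAsFactors = FALSE)
}
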