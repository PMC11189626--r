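#' Maze configuration
#'
#' Geometry and indexing conventions for a circular arena whose periphery
#' carries evenly spaced vestibules (entry chambers). Vestibules are indexed
#' `0..n_vestibules-1` in the clockwise direction, with the goal at
#' `goal_index` (0 in the goal-aligned frame used throughout). A vestibule
#' visit is detected when the animal's radial distance from the arena center
#' exceeds `visit_radius_cm`.
#'
#' @param n_vestibules Number of vestibules along the periphery (default 24).
#' @param goal_index Index of the goal vestibule (default 0).
#' @param visit_radius_cm Radial distance threshold (cm) separating the open
#'   arena from the vestibule zone (default 47.5).
#' @param arena_radius_cm Arena floor radius in cm (default 47.5; 95 cm wide
#'   floor).
#' @param sample_rate_hz Nominal trajectory sampling rate (default 25).
#' @return An object of class `"maze_config"`.
#' @examples
#' cfg <- maze_config()
#' circular_distance(23, 1, cfg)
#' @export
maze_config <- function(n_vestibules = 24L, goal_index = 0L,
                        visit_radius_cm = 47.5, arena_radius_cm = 47.5,
                        sample_rate_hz = 25) {
  n_vestibules <- as.integer(n_vestibules)
  goal_index <- as.integer(goal_index)
  if (n_vestibules < 3L)
    stop("n_vestibules must be at least 3")
  if (goal_index < 0L || goal_index >= n_vestibules)
    stop("goal_index must lie in 0..n_vestibules-1")
  if (visit_radius_cm <= 0)
    stop("visit_radius_cm must be positive")
  structure(
    list(n_vestibules = n_vestibules, goal_index = goal_index,
         visit_radius_cm = visit_radius_cm, arena_radius_cm = arena_radius_cm,
         sample_rate_hz = sample_rate_hz),
    class = "maze_config"
  )
}

#' @export
print.maze_config <- function(x, ...) {
  cat("Maze configuration:", x$n_vestibules, "vestibules, goal at",
      x$goal_index, "\n")
  cat("  visit radius:", x$visit_radius_cm, "cm;  sampling:",
      x$sample_rate_hz, "Hz\n")
  invisible(x)
}

check_vestibule <- function(v, config, what = "vestibule index") {
  v <- as.integer(v)
  if (anyNA(v) || any(v < 0L) || any(v >= config$n_vestibules))
    stop(what, " out of range 0..", config$n_vestibules - 1L)
  v
}

#' Circular door distance between two vestibules
#'
#' Shortest number of door-intervals separating two vestibules on the
#' circular arena, i.e. the graph distance on the n-cycle. For the default
#' 24-vestibule maze this lies in 0..12. Vectorized over `a` and `b`.
#'
#' @param a,b Vestibule indices (0-based), recycled to common length.
#' @param config A [maze_config()].
#' @return Integer vector of door distances.
#' @seealso [signed_displacement()] for the direction-signed version.
#' @export
circular_distance <- function(a, b, config = maze_config()) {
  a <- check_vestibule(a, config)
  b <- check_vestibule(b, config)
  n <- config$n_vestibules
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

#' Signed door displacement between two vestibules
#'
#' The segment size from vestibule `a` to vestibule `b`: the door distance
#' along the shorter travel direction, signed positive for clockwise travel
#' (indices increase clockwise) and negative for counterclockwise. The
#' antipodal tie (distance exactly n/2) resolves to the positive, clockwise
#' value, so for 24 vestibules the result lies in {-11..-1, 0, +1..+12},
#' with 0 only when `a == b`.
#'
#' @inheritParams circular_distance
#' @return Integer vector of signed displacements.
#' @export
signed_displacement <- function(a, b, config = maze_config()) {
  a <- check_vestibule(a, config)
  b <- check_vestibule(b, config)
  n <- config$n_vestibules
  s <- (b - a) %% n
  ifelse(s <= n %/% 2, s, s - n)
}

#' Single-trial container
#'
#' One navigation trial: a start vestibule and the ordered vestibules
#' visited afterwards, the last of which is the goal for a complete trial.
#' Consecutive visits never repeat (a zero-size segment is undefined).
#'
#' @param mouse_id Subject identifier.
#' @param day Session (day) index, 1-based.
#' @param trial Trial index within the session, 1-based.
#' @param start Start vestibule index.
#' @param visits Integer vector of visited vestibules, in order. May be empty
#'   only for the degenerate start-at-goal trial.
#' @param strategy_labels Optional per-segment strategy tags (same length as
#'   `visits`): ground truth from a generator or model-assigned.
#' @param truncated Logical; `TRUE` if the generating process hit its step
#'   guard before reaching the goal.
#' @param config A [maze_config()] used for validation.
#' @return An object of class `"maze_trial"`.
#' @export
maze_trial <- function(mouse_id, day, trial, start, visits,
                       strategy_labels = NULL, truncated = FALSE,
                       config = maze_config()) {
  start <- check_vestibule(start, config, "start")
  visits <- as.integer(visits)
  if (length(visits)) {
    check_vestibule(visits, config, "visit")
    if (visits[1L] == start)
      stop("first visit equals the start vestibule (zero-size segment)")
    if (length(visits) > 1L && any(diff(visits) == 0L))
      stop("consecutive visits repeat a vestibule (zero-size segment)")
  } else if (start != config$goal_index && !truncated) {
    stop("visits may be empty only when the trial starts at the goal")
  }
  if (!is.null(strategy_labels) && length(strategy_labels) != length(visits))
    stop("strategy_labels must have one entry per visit")
  structure(
    list(mouse_id = mouse_id, day = as.integer(day), trial = as.integer(trial),
         start = start, visits = visits, strategy_labels = strategy_labels,
         truncated = isTRUE(truncated)),
    class = "maze_trial"
  )
}

#' Is a trial complete (ends at the goal)?
#'
#' @param trial A [maze_trial()].
#' @param config A [maze_config()].
#' @return Logical scalar.
#' @export
is_complete <- function(trial, config = maze_config()) {
  if (trial$truncated) return(FALSE)
  if (!length(trial$visits)) return(trial$start == config$goal_index)
  trial$visits[length(trial$visits)] == config$goal_index
}

#' @export
print.maze_trial <- function(x, ...) {
  cat(sprintf("Trial (mouse %s, day %d, trial %d): start %d -> [%s]%s\n",
              as.character(x$mouse_id), x$day, x$trial, x$start,
              paste(x$visits, collapse = " "),
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Dataset of trials
#'
#' A flat collection of [maze_trial()] objects with (mouse_id, day, trial)
#' unique, plus free-form metadata (group labels, generating parameters,
#' seed). Stored columnwise for fast summarization: parallel vectors for the
#' identifiers and start positions and a list of visit vectors.
#'
#' @param trials A list of [maze_trial()] objects.
#' @param metadata Named list of provenance information.
#' @param config A [maze_config()].
#' @return An object of class `"maze_dataset"`.
#' @export
maze_dataset <- function(trials, metadata = list(), config = maze_config()) {
  stopifnot(is.list(trials), length(trials) > 0L)
  mouse_id <- vapply(trials, function(tr) as.character(tr$mouse_id), "")
  day <- vapply(trials, function(tr) tr$day, 0L)
  trial <- vapply(trials, function(tr) tr$trial, 0L)
  key <- paste(mouse_id, day, trial, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (mouse_id, day, trial) keys in dataset")
  structure(
    list(mouse_id = mouse_id, day = day, trial = trial,
         start = vapply(trials, function(tr) tr$start, 0L),
         visits = lapply(trials, function(tr) tr$visits),
         strategy_labels = lapply(trials, function(tr) tr$strategy_labels),
         truncated = vapply(trials, function(tr) tr$truncated, FALSE),
         metadata = metadata, config = config),
    class = "maze_dataset"
  )
}

new_maze_dataset <- function(mouse_id, day, trial, start, visits,
                             strategy_labels = NULL, truncated = NULL,
                             metadata = list(), config = maze_config()) {
  n <- length(start)
  structure(
    list(mouse_id = as.character(mouse_id), day = as.integer(day),
         trial = as.integer(trial), start = as.integer(start),
         visits = visits,
         strategy_labels = if (is.null(strategy_labels))
           vector("list", n) else strategy_labels,
         truncated = if (is.null(truncated)) logical(n) else truncated,
         metadata = metadata, config = config),
    class = "maze_dataset"
  )
}

#' @export
length.maze_dataset <- function(x) length(x$start)

#' Extract one trial from a dataset
#'
#' @param dataset A [maze_dataset()].
#' @param i Trial position (1-based row).
#' @return A [maze_trial()].
#' @export
dataset_trial <- function(dataset, i) {
  maze_trial(dataset$mouse_id[i], dataset$day[i], dataset$trial[i],
             dataset$start[i], dataset$visits[[i]],
             strategy_labels = dataset$strategy_labels[[i]],
             truncated = dataset$truncated[i], config = dataset$config)
}

#' Subset a dataset by day or arbitrary index
#'
#' @param dataset A [maze_dataset()].
#' @param days Integer vector of days to keep, or `NULL`.
#' @param idx Logical or integer index over trials, or `NULL`.
#' @return A [maze_dataset()].
#' @export
subset_dataset <- function(dataset, days = NULL, idx = NULL) {
  keep <- rep(TRUE, length(dataset))
  if (!is.null(days)) keep <- keep & dataset$day %in% days
  if (!is.null(idx)) {
    sel <- rep(FALSE, length(dataset))
    sel[idx] <- TRUE
    keep <- keep & sel
  }
  new_maze_dataset(dataset$mouse_id[keep], dataset$day[keep],
                   dataset$trial[keep], dataset$start[keep],
                   dataset$visits[keep], dataset$strategy_labels[keep],
                   dataset$truncated[keep], dataset$metadata, dataset$config)
}

#' @export
print.maze_dataset <- function(x, ...) {
  compl <- vapply(seq_along(x$start), function(i) {
    v <- x$visits[[i]]
    !x$truncated[i] &&
      ((length(v) && v[length(v)] == x$config$goal_index) ||
         (!length(v) && x$start[i] == x$config$goal_index))
  }, FALSE)
  cat(sprintf(paste0("Maze dataset: %d trials, %d mice, days %s",
                     " (%d incomplete)\n"),
              length(x), length(unique(x$mouse_id)),
              paste(range(x$day), collapse = "-"), sum(!compl)))
  invisible(x)
}

#' Convert a dataset to a long data frame of visit sequences
#'
#' One row per step; `step_index` 0 is the start vestibule, subsequent rows
#' are visits in order. This is the on-disk sequence format, see
#' [write_sequences()].
#'
#' @param x A [maze_dataset()].
#' @param ... Unused.
#' @return A data frame with columns `mouse_id, day, trial, step_index,
#'   vestibule`.
#' @export
as.data.frame.maze_dataset <- function(x, ...) {
  lens <- lengths(x$visits) + 1L
  i <- rep.int(seq_along(x$start), lens)
  step <- sequence(lens) - 1L
  vest <- integer(sum(lens))
  vest[step == 0L] <- x$start
  vest[step > 0L] <- unlist(x$visits, use.names = FALSE)
  data.frame(mouse_id = x$mouse_id[i], day = x$day[i], trial = x$trial[i],
             step_index = step, vestibule = vest,
             stringsAsFactors = FALSE)
}

# TRUE per trial: ends at goal and not truncated
complete_mask <- function(dataset) {
  goal <- dataset$config$goal_index
  last <- vapply(dataset$visits, function(v)
    if (length(v)) v[length(v)] else NA_integer_, 0L)
  ok <- !dataset$truncated & !is.na(last) & last == goal
  ok | (!dataset$truncated & is.na(last) & dataset$start == goal)
}
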