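#' Rule-based trial classifier
#'
#' The simple trial-wise criteria used in classic hole-board studies:
#' a trial is *serial* if the goal is reached via a terminal direction-pure
#' serial bout of at least `serial_min_bout` unit segments; otherwise
#' *spatial* if the trial length (number of vestibule visits) is below
#' `spatial_max_visits`; otherwise *random*. Serial takes precedence, so a
#' short all-serial trial is labelled serial, and non-serial trials of
#' length exactly `spatial_max_visits` are labelled random.
#'
#' @param trial A complete [maze_trial()] (ends at the goal).
#' @param config A [maze_config()].
#' @param spatial_max_visits Exclusive visit-count bound for the spatial
#'   label (default 3).
#' @param serial_min_bout Minimal terminal bout length for the serial label
#'   (default 3).
#' @return One of `"spatial"`, `"serial"`, `"random"`.
#' @examples
#' classify_trial(maze_trial("m", 1, 1, 2, c(1, 0)))        # spatial
#' classify_trial(maze_trial("m", 1, 1, 21, c(22, 23, 0)))  # serial
#' @export
classify_trial <- function(trial, config = maze_config(),
                           spatial_max_visits = 3L, serial_min_bout = 3L) {
  if (spatial_max_visits < 1L || serial_min_bout < 1L)
    stop("classifier thresholds must be >= 1")
  if (!is_complete(trial, config))
    stop("classify_trial requires a complete trial")
  seg <- trial_segments(trial, config)
  L <- length(seg)
  if (L >= serial_min_bout) {
    r <- rle(seg)
    last <- length(r$values)
    if (abs(r$values[last]) == 1L && r$lengths[last] >= serial_min_bout)
      return("serial")
  }
  if (L < spatial_max_visits) return("spatial")
  "random"
}

#' Classify every complete trial of a dataset
#'
#' @param dataset A [maze_dataset()].
#' @inheritParams classify_trial
#' @return A data frame with columns `mouse_id, day, trial, label`
#'   (incomplete trials excluded with a message).
#' @export
classify_trials <- function(dataset, config = dataset$config,
                            spatial_max_visits = 3L, serial_min_bout = 3L) {
  ok <- complete_mask(dataset)
  if (!all(ok))
    message(sum(!ok), " incomplete trial(s) excluded from classification")
  idx <- which(ok)
  label <- vapply(idx, function(i)
    classify_trial(dataset_trial(dataset, i), config,
                   spatial_max_visits, serial_min_bout), "")
  data.frame(mouse_id = dataset$mouse_id[idx], day = dataset$day[idx],
             trial = dataset$trial[idx], label = label,
             stringsAsFactors = FALSE)
}

#' Per-day strategy-label proportions
#'
#' Applies [classify_trial()] to every complete trial and tabulates label
#' proportions by day (rows sum to 1).
#'
#' @inheritParams classify_trials
#' @return A data frame with columns `day, spatial, serial, random,
#'   n_trials`.
#' @export
classify_dataset <- function(dataset, config = dataset$config,
                             spatial_max_visits = 3L, serial_min_bout = 3L) {
  labs <- classify_trials(dataset, config, spatial_max_visits,
                          serial_min_bout)
  days <- sort(unique(labs$day))
  out <- do.call(rbind, lapply(days, function(d) {
    sub <- labs$label[labs$day == d]
    data.frame(day = d,
               spatial = mean(sub == "spatial"),
               serial = mean(sub == "serial"),
               random = mean(sub == "random"),
               n_trials = length(sub))
  }))
  out
}
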