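#' Detect vestibule visits in an xy trajectory
#'
#' A visit opens when the radial distance from the arena center crosses
#' `visit_radius_cm` outward and closes at the next inward crossing.
#' Vestibule identity is the nearest of the `n_vestibules` sector centers
#' (15 degrees apart for 24 vestibules) by the trajectory angle while
#' outside the threshold. Consecutive events in the same vestibule are
#' merged when the trajectory between them never retreats more than
#' `merge_depth_cm` below the threshold (a debounce against jitter-induced
#' splitting of one physical visit; genuine returns toward the arena
#' center travel far deeper than the debounce depth).
#'
#' Sector centers follow the package convention that vestibule indices
#' increase clockwise: vestibule v sits at angle `-v * 360 / n` degrees,
#' with the goal vestibule at angle 0.
#'
#' @param traj A data frame with numeric columns `t` (seconds) and `x`, `y`
#'   (cm, arena-centered, goal-aligned frame).
#' @param config A [maze_config()].
#' @param merge_depth_cm Debounce depth in cm (default 3).
#' @return A data frame with columns `vestibule`, `t_enter`, `t_exit`, one
#'   row per visit in time order (zero rows if the threshold is never
#'   crossed).
#' @export
detect_vestibule_visits <- function(traj, config = maze_config(),
                                    merge_depth_cm = 3) {
  if (!all(c("t", "x", "y") %in% names(traj)))
    stop("traj must have columns t, x, y")
  if (nrow(traj) == 0L) stop("empty trajectory")
  r <- sqrt(traj$x^2 + traj$y^2)
  out <- r >= config$visit_radius_cm
  if (!any(out))
    return(data.frame(vestibule = integer(0), t_enter = numeric(0),
                      t_exit = numeric(0)))
  runs <- rle(out)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]
  ends <- ends[keep]
  n <- config$n_vestibules
  sector <- 360 / n
  vest <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    # mean direction over the excursion is robust to jitter at the crossing
    ang <- atan2(mean(traj$y[seg]), mean(traj$x[seg])) * 180 / pi
    as.integer(round(-ang / sector)) %% n
  }, 0L)
  t_enter <- traj$t[starts]
  t_exit <- traj$t[ends]
  # merge same-vestibule events separated only by a shallow dip
  if (length(vest) > 1L) {
    keep_row <- rep(TRUE, length(vest))
    for (i in 2:length(vest)) {
      j <- max(which(keep_row[1:(i - 1L)]))
      if (vest[i] == vest[j]) {
        gap <- (ends[j] + 1L):(starts[i] - 1L)
        if (length(gap) == 0L ||
            min(r[gap]) > config$visit_radius_cm - merge_depth_cm) {
          t_exit[j] <- t_exit[i]
          ends[j] <- ends[i]
          keep_row[i] <- FALSE
        }
      }
    }
    vest <- vest[keep_row]
    t_enter <- t_enter[keep_row]
    t_exit <- t_exit[keep_row]
  }
  data.frame(vestibule = vest, t_enter = t_enter, t_exit = t_exit)
}

#' Path length of a trajectory piece
#'
#' Sum of per-sample Euclidean displacements.
#'
#' @param x,y Numeric coordinate vectors (cm) of equal length.
#' @return Path length in cm (0 for fewer than two samples).
#' @export
path_length <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Signed segment sizes of a visit sequence
#'
#' Segment i is the signed door displacement from the previously occupied
#' vestibule (the start for i = 1) to visit i; the trial length is the
#' number of segments. Sizes lie in -11..-1, +1..+12 (antipodal ties are
#' clockwise by convention); a zero size is a contract violation.
#'
#' @param start Start vestibule index.
#' @param visits Ordered integer vector of visited vestibules.
#' @param config A [maze_config()].
#' @return Integer vector of signed segment sizes, one per visit.
#' @examples
#' segments_from_visits(22, c(23, 0))  # two clockwise unit steps
#' @export
segments_from_visits <- function(start, visits, config = maze_config()) {
  visits <- as.integer(visits)
  if (!length(visits)) return(integer(0))
  prev <- c(as.integer(start), visits[-length(visits)])
  seg <- signed_displacement(prev, visits, config)
  if (any(seg == 0L))
    stop("consecutive equal vestibules: segment size 0 is undefined")
  seg
}

#' Segment sizes of a trial
#'
#' @param trial A [maze_trial()].
#' @param config A [maze_config()].
#' @return Integer vector of signed segment sizes.
#' @export
trial_segments <- function(trial, config = maze_config()) {
  segments_from_visits(trial$start, trial$visits, config)
}

#' Serial bout lengths
#'
#' A serial bout is a maximal run of consecutive segments of size exactly
#' one door-interval in a single direction: +1 runs and -1 runs are
#' distinct, so a direction change breaks a bout. Isolated unit segments
#' count as bouts of length 1.
#'
#' @param segments Integer vector of signed segment sizes (one trial).
#' @return Integer vector of bout lengths in order of occurrence (possibly
#'   empty).
#' @examples
#' serial_bouts(c(1, 1, 1, -3, 1, 1))  # 3, 2
#' serial_bouts(c(1, -1, 1))           # 1, 1, 1
#' @export
serial_bouts <- function(segments) {
  if (!length(segments)) return(integer(0))
  r <- rle(as.integer(segments))
  r$lengths[r$values == 1L | r$values == -1L]
}

#' Segment a trajectory into a trial
#'
#' Convenience wrapper: detects vestibule visits in an xy trajectory and
#' interprets the first visit as the start vestibule (trials begin inside
#' the start vestibule, beyond the radial threshold).
#'
#' @param traj Trajectory data frame (see [detect_vestibule_visits()]),
#'   optionally carrying `mouse_id`, `day`, `trial` columns.
#' @param config A [maze_config()].
#' @param ... Passed to [detect_vestibule_visits()].
#' @return A [maze_trial()].
#' @export
segment_trajectory <- function(traj, config = maze_config(), ...) {
  ev <- detect_vestibule_visits(traj, config, ...)
  if (nrow(ev) < 1L) stop("trajectory contains no vestibule visit")
  meta <- function(col, default) if (col %in% names(traj)) traj[[col]][1L] else default
  maze_trial(meta("mouse_id", "m1"), meta("day", 1L), meta("trial", 1L),
             start = ev$vestibule[1L], visits = ev$vestibule[-1L],
             config = config)
}
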