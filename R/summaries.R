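#' @name summaries
#' @title Summary distributions of vestibule sequences
#' @description
#' Four normalized distributions characterize a set of trials and serve as
#' fitting targets: trial length (number of segments per trial, capped with
#' overflow pooled into the top bin), vestibule occupancy (proportion of
#' visits per vestibule), signed segment size (-12..+12 excluding 0), and
#' serial bout length (capped, overflow pooled). Their per-segment-index
#' variants resolve the first K segment positions of each trial separately.
NULL

SUMMARY_COMPONENTS <- c("trial_length", "vestibule_visits", "segment_size",
                        "serial_bout")
PER_INDEX_COMPONENTS <- c("segment_size_by_index", "vestibule_by_index")

# Pool complete trials of a dataset into flat vectors:
# lengths (per trial), v_all (visits), prev_all, seg_all, pos (segment index
# within trial). Incomplete trials are dropped with a message.
pool_dataset <- function(dataset, quiet = FALSE) {
  ok <- complete_mask(dataset)
  if (!all(ok) && !quiet)
    message(sum(!ok), " incomplete trial(s) excluded from summaries")
  if (!any(ok)) stop("no complete trials to summarize")
  starts <- dataset$start[ok]
  visits <- dataset$visits[ok]
  lens <- lengths(visits)
  keep <- lens > 0L  # degenerate start-at-goal trials carry no segments
  pool_from_list(starts[keep], visits[keep], dataset$config)
}

pool_from_list <- function(starts, visits, config) {
  lens <- lengths(visits)
  v_all <- unlist(visits, use.names = FALSE)
  finish_pool(starts, lens, v_all, config)
}

# visits stored columnwise in a matrix (simulation engine output)
pool_from_matrix <- function(starts, lens, vis, config) {
  keep <- lens > 0L
  starts <- starts[keep]
  lens <- lens[keep]
  vis <- vis[, keep, drop = FALSE]
  total <- sum(lens)
  col_id <- rep.int(seq_along(lens), lens)
  pos <- sequence(lens)
  v_all <- vis[pos + (col_id - 1L) * nrow(vis)]
  finish_pool(starts, lens, v_all, config, pos, col_id)
}

finish_pool <- function(starts, lens, v_all, config, pos = NULL,
                        col_id = NULL) {
  total <- length(v_all)
  if (is.null(col_id)) col_id <- rep.int(seq_along(lens), lens)
  if (is.null(pos)) pos <- sequence(lens)
  prev_all <- c(NA_integer_, v_all[-total])
  first <- pos == 1L
  prev_all[first] <- starts[col_id[first]]
  n <- config$n_vestibules
  s <- (v_all - prev_all) %% n
  seg_all <- ifelse(s <= n %/% 2L, s, s - n)
  list(n_trials = length(lens), lengths = lens, v_all = v_all,
       seg_all = seg_all, pos = pos, col_id = col_id, config = config)
}

# proportions of segment sizes over bins -12..-1, +1..+12 (24 bins)
seg_bin <- function(seg) ifelse(seg < 0L, seg + 13L, seg + 12L)

seg_bin_names <- function() as.character(c(-12:-1, 1:12))

# serial bout lengths pooled across trials, respecting trial boundaries
pooled_bouts <- function(pool) {
  z <- pool$seg_all
  unit <- z == 1L | z == -1L
  if (!any(unit)) return(integer(0))
  total <- length(z)
  prev_z <- c(NA_integer_, z[-total])
  new_run <- unit & (pool$pos == 1L | is.na(prev_z) | prev_z != z)
  rid <- cumsum(new_run)[unit]
  tabulate(rid, nbins = max(rid))
}

summaries_from_pool <- function(pool, trial_cap = 30L, bout_cap = 15L) {
  nv <- pool$config$n_vestibules
  tl <- tabulate(pmin(pool$lengths, trial_cap), nbins = trial_cap)
  vv <- tabulate(pool$v_all + 1L, nbins = nv)
  ss <- tabulate(seg_bin(pool$seg_all), nbins = 24L)
  bouts <- pooled_bouts(pool)
  sb <- if (length(bouts))
    tabulate(pmin(bouts, bout_cap), nbins = bout_cap) else numeric(bout_cap)
  norm <- function(x) if (sum(x) > 0) x / sum(x) else as.numeric(x)
  structure(
    list(trial_length = stats::setNames(norm(tl), seq_len(trial_cap)),
         vestibule_visits = stats::setNames(norm(vv), seq_len(nv) - 1L),
         segment_size = stats::setNames(norm(ss), seg_bin_names()),
         serial_bout = stats::setNames(norm(sb), seq_len(bout_cap))),
    class = "summary_set", n_trials = pool$n_trials)
}

per_index_from_pool <- function(pool, K = 10L) {
  nv <- pool$config$n_vestibules
  ssm <- matrix(0, K, 24L,
                dimnames = list(seq_len(K), seg_bin_names()))
  vvm <- matrix(0, K, nv, dimnames = list(seq_len(K), seq_len(nv) - 1L))
  for (k in seq_len(K)) {
    sel <- pool$pos == k
    cnt <- sum(sel)
    if (cnt == 0L) next
    ssm[k, ] <- tabulate(seg_bin(pool$seg_all[sel]), nbins = 24L) / cnt
    vvm[k, ] <- tabulate(pool$v_all[sel] + 1L, nbins = nv) / cnt
  }
  structure(list(segment_size_by_index = ssm, vestibule_by_index = vvm),
            class = "per_index_summary", K = K)
}

#' Summary distributions of a dataset
#'
#' Pools all complete trials and computes the four normalized summary
#' distributions. Incomplete (truncated or non-goal-terminated) trials are
#' excluded with a message.
#'
#' @param dataset A [maze_dataset()].
#' @param trial_cap Top bin of the trial-length distribution (default 30);
#'   longer trials pool into it.
#' @param bout_cap Top bin of the serial-bout distribution (default 15).
#' @param quiet Suppress the excluded-trial message.
#' @return An object of class `"summary_set"`: a named list of probability
#'   vectors `trial_length`, `vestibule_visits`, `segment_size`,
#'   `serial_bout`.
#' @export
summarize_dataset <- function(dataset, trial_cap = 30L, bout_cap = 15L,
                              quiet = FALSE) {
  summaries_from_pool(pool_dataset(dataset, quiet = quiet),
                      trial_cap = trial_cap, bout_cap = bout_cap)
}

#' Per-segment-index summary distributions
#'
#' Distributions of segment size and visited vestibule resolved by segment
#' position for the first `K` segments of each trial. Rows at positions
#' beyond a trial's length simply receive no mass from that trial; a row
#' with no observations at all is left as zeros.
#'
#' @inheritParams summarize_dataset
#' @param K Number of leading segment positions (default 10).
#' @return An object of class `"per_index_summary"`: `K x 24` matrix
#'   `segment_size_by_index` and `K x n_vestibules` matrix
#'   `vestibule_by_index`, rows normalized where populated.
#' @export
summarize_per_index <- function(dataset, K = 10L, quiet = FALSE) {
  per_index_from_pool(pool_dataset(dataset, quiet = quiet), K = K)
}

#' @export
print.summary_set <- function(x, ...) {
  cat("Summary distributions over", attr(x, "n_trials"), "trials\n")
  cat("  mean trial length:",
      round(sum(as.numeric(names(x$trial_length)) * x$trial_length), 2), "\n")
  cat("  goal-vestibule visit share:",
      round(x$vestibule_visits[["0"]], 3), "\n")
  cat("  unit-segment share:",
      round(x$segment_size[["1"]] + x$segment_size[["-1"]], 3), "\n")
  invisible(x)
}

#' @export
plot.summary_set <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$trial_length, main = "Trial length",
                    xlab = "segments per trial", ylab = "proportion", ...)
  graphics::barplot(x$vestibule_visits, main = "Vestibule visits",
                    xlab = "vestibule (goal = 0)", ylab = "proportion", ...)
  graphics::barplot(x$segment_size, main = "Segment size",
                    xlab = "door-intervals (+ = clockwise)",
                    ylab = "proportion", ...)
  graphics::barplot(x$serial_bout, main = "Serial bout length",
                    xlab = "segments per bout", ylab = "proportion", ...)
  invisible(x)
}

#' Mean squared error between summary distributions
#'
#' Mean of squared bin-wise differences pooled over all bins of the
#' components shared by `a` and `b` (equal bin weight): the comparator used
#' by both the mixture grid search and the genetic algorithm. Inputs may be
#' `"summary_set"` objects, `"per_index_summary"` objects, or plain named
#' lists mixing both kinds of component.
#'
#' @param a,b Summary objects of matching shape.
#' @param components Optional character vector restricting which components
#'   enter the error.
#' @return A scalar mean squared error (>= 0).
#' @examples
#' s <- list(trial_length = c(0.5, 0.5))
#' summary_mse(s, s)  # 0
#' @export
summary_mse <- function(a, b, components = NULL) {
  a <- unclass(a)
  b <- unclass(b)
  if (is.null(components)) components <- intersect(names(a), names(b))
  if (!length(components)) stop("no shared components to compare")
  if (!all(components %in% names(a)) || !all(components %in% names(b)))
    stop("missing component(s): ",
         paste(setdiff(components, intersect(names(a), names(b))),
               collapse = ", "))
  ua <- unlist(a[components], use.names = FALSE)
  ub <- unlist(b[components], use.names = FALSE)
  if (length(ua) != length(ub))
    stop("component shapes differ between a and b")
  mean((ua - ub)^2)
}

#' Objective summaries for model fitting
#'
#' Computes, in one pass, the subset of summary components named in
#' `components` — any mix of the four pooled distributions and the two
#' per-index matrices. This is what the fitting routines compare via
#' [summary_mse()].
#'
#' @inheritParams summarize_dataset
#' @param components Character vector of component names (see
#'   [summary_mse()]). Defaults to the four pooled distributions.
#' @param K Segment positions for the per-index components.
#' @return A plain named list of the requested components.
#' @export
summarize_objective <- function(dataset,
                                components = SUMMARY_COMPONENTS,
                                trial_cap = 30L, bout_cap = 15L, K = 10L,
                                quiet = TRUE) {
  pool <- pool_dataset(dataset, quiet = quiet)
  objective_from_pool(pool, components, trial_cap, bout_cap, K)
}

objective_from_pool <- function(pool, components, trial_cap = 30L,
                                bout_cap = 15L, K = 10L) {
  out <- list()
  if (any(components %in% SUMMARY_COMPONENTS))
    out <- unclass(summaries_from_pool(pool, trial_cap, bout_cap))
  if (any(components %in% PER_INDEX_COMPONENTS))
    out <- c(out, unclass(per_index_from_pool(pool, K)))
  bad <- setdiff(components, names(out))
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
  out[components]
}

#' Export summary distributions as a tidy data frame
#'
#' @param x A `"summary_set"` or plain objective list.
#' @return A data frame with columns `component`, `bin`, `proportion`.
#' @export
summary_to_df <- function(x) {
  x <- unclass(x)
  do.call(rbind, lapply(names(x), function(nm) {
    v <- x[[nm]]
    if (is.matrix(v)) {
      data.frame(component = nm,
                 bin = paste(rep(rownames(v), ncol(v)),
                             rep(colnames(v), each = nrow(v)), sep = ":"),
                 proportion = as.vector(v), stringsAsFactors = FALSE)
    } else {
      data.frame(component = nm, bin = names(v), proportion = unname(v),
                 stringsAsFactors = FALSE)
    }
  }))
}
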