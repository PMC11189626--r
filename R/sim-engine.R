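# Vectorized trial-simulation engines.
#
# Both models generate many trials simultaneously: the loop runs over
# segment steps, and at each step the next vestibule is drawn for all still-
# active trials at once, grouped by current strategy. Output is columnwise
# (visits matrix, one column per trial) and feeds pool_from_matrix() without
# per-trial allocation, which is what keeps exhaustive grid search and the
# genetic algorithm affordable.

grow_rows <- function(m, new_cap) {
  out <- matrix(NA_integer_, new_cap, ncol(m))
  out[seq_len(nrow(m)), ] <- m
  out
}

# Mixture model: strategy codes 1 = random, 2 = serial (unified),
# 3 = spatial; probs = c(p_random, p_serial, p_spatial) in percent.
sim_mixture_engine <- function(starts, probs, n_persist, config, sp,
                               want_labels = FALSE,
                               guard = sp$max_steps_per_trial) {
  starts <- as.integer(starts)
  n_tr <- length(starts)
  goal <- config$goal_index
  cur <- starts
  active <- which(cur != goal)
  lens <- integer(n_tr)
  truncated <- logical(n_tr)
  cap <- 64L
  vis <- matrix(NA_integer_, cap, n_tr)
  lab <- if (want_labels) matrix(NA_integer_, cap, n_tr) else NULL
  block_left <- integer(n_tr)
  strat <- integer(n_tr)
  p_r <- probs[1L]
  p_sp <- probs[3L]
  step <- 0L
  while (length(active)) {
    step <- step + 1L
    if (step > guard) {
      truncated[active] <- TRUE
      break
    }
    if (step > cap) {
      cap <- cap * 2L
      vis <- grow_rows(vis, cap)
      if (want_labels) lab <- grow_rows(lab, cap)
    }
    nb <- active[block_left[active] == 0L]
    if (length(nb)) {
      u <- stats::runif(length(nb)) * 100
      strat[nb] <- ifelse(u < p_r, 1L, ifelse(u >= p_r + p_sp, 2L, 3L))
      block_left[nb] <- n_persist
    }
    st <- strat[active]
    nxt <- integer(length(active))
    g <- st == 1L
    if (any(g)) nxt[g] <- draw_random_step(cur[active[g]], config)
    g <- st == 2L
    if (any(g))
      nxt[g] <- draw_serial_step(cur[active[g]], config, sp$serial,
                                 "unified")$vestibule
    g <- st == 3L
    if (any(g)) nxt[g] <- draw_spatial_step(cur[active[g]], config, sp$spatial)
    vis[step, active] <- nxt
    if (want_labels) lab[step, active] <- st
    cur[active] <- nxt
    lens[active] <- step
    block_left[active] <- block_left[active] - 1L
    active <- active[nxt != goal]
  }
  list(starts = starts, lengths = lens, visits = vis, labels = lab,
       truncated = truncated)
}

# Markov chain model: strategy codes 1 = random, 2 = serial clockwise,
# 3 = serial counterclockwise, 4 = spatial. mat is the 5x4 matrix whose
# first row holds initial-strategy probabilities and rows 2..5 the
# transition rows.
sim_markov_engine <- function(starts, mat, config, sp, want_labels = FALSE,
                              guard = sp$max_steps_per_trial) {
  starts <- as.integer(starts)
  n_tr <- length(starts)
  goal <- config$goal_index
  cur <- starts
  active <- which(cur != goal)
  lens <- integer(n_tr)
  truncated <- logical(n_tr)
  cap <- 64L
  vis <- matrix(NA_integer_, cap, n_tr)
  lab <- if (want_labels) matrix(NA_integer_, cap, n_tr) else NULL
  strat <- integer(n_tr)
  cum_init <- cumsum(mat[1L, ])[1:3]
  cum_trans <- t(apply(mat[2:5, , drop = FALSE], 1L, cumsum))[, 1:3,
                                                             drop = FALSE]
  step <- 0L
  while (length(active)) {
    step <- step + 1L
    if (step > guard) {
      truncated[active] <- TRUE
      break
    }
    if (step > cap) {
      cap <- cap * 2L
      vis <- grow_rows(vis, cap)
      if (want_labels) lab <- grow_rows(lab, cap)
    }
    if (step == 1L) {
      u <- stats::runif(length(active))
      strat[active] <- 1L + findInterval(u, cum_init)
    } else {
      prev <- strat[active]
      for (gidx in 1:4) {
        sel <- active[prev == gidx]
        if (length(sel)) {
          u <- stats::runif(length(sel))
          strat[sel] <- 1L + findInterval(u, cum_trans[gidx, ])
        }
      }
    }
    st <- strat[active]
    nxt <- integer(length(active))
    g <- st == 1L
    if (any(g)) nxt[g] <- draw_random_step(cur[active[g]], config)
    g <- st == 2L
    if (any(g))
      nxt[g] <- draw_serial_step(cur[active[g]], config, sp$serial,
                                 "cw")$vestibule
    g <- st == 3L
    if (any(g))
      nxt[g] <- draw_serial_step(cur[active[g]], config, sp$serial,
                                 "ccw")$vestibule
    g <- st == 4L
    if (any(g)) nxt[g] <- draw_spatial_step(cur[active[g]], config, sp$spatial)
    vis[step, active] <- nxt
    if (want_labels) lab[step, active] <- st
    cur[active] <- nxt
    lens[active] <- step
    active <- active[nxt != goal]
  }
  list(starts = starts, lengths = lens, visits = vis, labels = lab,
       truncated = truncated)
}

# Wrap an engine result into a maze_dataset, keyed by a schedule data frame
# (columns mouse_id, day, trial, one row per simulated trial).
engine_to_dataset <- function(eng, schedule, label_levels, metadata, config) {
  n <- length(eng$starts)
  visits <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    len <- eng$lengths[i]
    if (len > 0L) {
      visits[[i]] <- eng$visits[seq_len(len), i]
      if (!is.null(eng$labels))
        labels[[i]] <- label_levels[eng$labels[seq_len(len), i]]
    } else {
      visits[[i]] <- integer(0)
    }
  }
  new_maze_dataset(schedule$mouse_id, schedule$day, schedule$trial,
                   eng$starts, visits,
                   strategy_labels = labels, truncated = eng$truncated,
                   metadata = metadata, config = config)
}
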