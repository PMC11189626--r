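# shared fixtures: everything is generated in code at test time

cfg <- maze_config()

# a flat schedule of n trials with starts at least min_d doors from the goal
test_schedule <- function(n, min_d = 2L, config = cfg) {
  v <- seq_len(config$n_vestibules) - 1L
  allowed <- v[circular_distance(v, config$goal_index, config) >= min_d]
  data.frame(mouse_id = sprintf("m%02d", rep(seq_len(ceiling(n / 10)),
                                             each = 10L))[seq_len(n)],
             day = 1L,
             trial = rep(1:10, length.out = n),
             start = allowed[sample.int(length(allowed), n, replace = TRUE)],
             stringsAsFactors = FALSE)
}

# dataset holding explicitly scripted trials
scripted_dataset <- function(starts, visits_list, config = cfg) {
  trials <- lapply(seq_along(starts), function(i)
    maze_trial(sprintf("m%02d", i), 1L, i, starts[i], visits_list[[i]],
               config = config))
  maze_dataset(trials, config = config)
}

# brute-force shortest path on the n-cycle: walk both directions
oracle_cycle_distance <- function(a, b, n = 24L) {
  cw <- (b - a) %% n
  ccw <- (a - b) %% n
  min(cw, ccw)
}
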