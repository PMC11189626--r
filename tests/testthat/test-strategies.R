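test_that("random draw is uniform over the 23 other vestibules and reproducible", {
  set.seed(101)
  draws <- draw_random_step(rep(5L, 100000L), cfg)
  expect_true(all(draws != 5L))
  counts <- tabulate(draws + 1L, 24)[-6]  # drop the impossible current bin
  gof <- chisq.test(counts, p = rep(1 / 23, 23))
  expect_gt(gof$p.value, 0.001)
  set.seed(77)
  a <- draw_random_step(rep(3L, 100L), cfg)
  set.seed(77)
  b <- draw_random_step(rep(3L, 100L), cfg)
  expect_identical(a, b)
})

test_that("spatial weights follow the symmetric exponential of goal distance", {
  w <- spatial_weights(cfg, spatial_params(tau = 2))
  expect_equal(w[1], 1)                  # exp(0) at the goal
  expect_equal(w[3], exp(-1))            # distance 2, tau 2
  expect_equal(w[2:12], w[24:14])        # symmetry about the goal
  expect_equal(which.max(w), 1L)
})

test_that("spatial step probabilities equal the enumeration oracle for every current", {
  tau <- 2
  for (cur in 0:23) {
    # independent enumeration: unnormalized weight per candidate, current removed
    w <- vapply(0:23, function(v) {
      if (v == cur) return(0)
      exp(-oracle_cycle_distance(v, 0) / tau)
    }, 0)
    expect_equal(spatial_step_probs(cur, cfg, spatial_params(tau)), w / sum(w))
  }
})

test_that("spatial draws match their exact distribution and never repeat the current vestibule", {
  set.seed(202)
  cur <- 5L
  draws <- draw_spatial_step(rep(cur, 100000L), cfg)
  expect_true(all(draws != cur))
  p <- spatial_step_probs(cur, cfg)
  counts <- tabulate(draws + 1L, 24)[-(cur + 1L)]
  gof <- chisq.test(counts, p = p[-(cur + 1L)])
  expect_gt(gof$p.value, 0.001)
  expect_identical(which.max(tabulate(draws + 1L, 24)) - 1L, cfg$goal_index)
})

test_that("unified serial sign bias is 80% clockwise", {
  set.seed(303)
  s <- draw_serial_step(rep(10L, 10000L), cfg, serial_params(), "unified")$step
  frac_pos <- mean(s > 0)
  tol <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(frac_pos - 0.8), tol)
})

test_that("direction-fixed serial steps match the rounded-truncated normal oracle", {
  set.seed(404)
  s <- draw_serial_step(rep(10L, 100000L), cfg, serial_params(), "cw")$step
  expect_true(all(s >= 1L))
  # rejection-sampling oracle: round(1.2 + 1.2 z), keep only positive values
  z <- round(1.2 + 1.2 * rnorm(400000))
  z <- z[z >= 1][seq_len(100000)]
  top <- 6L  # pool the sparse tail
  bin <- function(v) tabulate(pmin(v, top), top)
  o <- bin(z)
  gof <- chisq.test(bin(s), p = o / sum(o))
  expect_gt(gof$p.value, 0.001)
  set.seed(405)
  s2 <- draw_serial_step(rep(10L, 5000L), cfg, serial_params(), "ccw")$step
  expect_true(all(s2 <= -1L))
})

test_that("serial next vestibule is current plus step, never current itself", {
  set.seed(505)
  cur <- sample(0:23, 5000, replace = TRUE)
  d <- draw_serial_step(cur, cfg, serial_params(), "unified")
  expect_identical(d$vestibule, (cur + d$step) %% 24L)
  expect_true(all(d$vestibule != cur))
})

test_that("pure random trials have geometric mean length 23", {
  set.seed(606)
  sched <- test_schedule(10000)
  ds <- simulate_mixture_dataset(mixture_params(100, 0, 0, 6), sched,
                                 labels = FALSE)
  lens <- lengths(ds$visits)
  # geometric oracle: success probability 1/23, mean 23, sd sqrt(1-p)/p
  sem <- (sqrt(1 - 1 / 23) * 23) / sqrt(10000)
  expect_lt(abs(mean(lens) - 23), 3 * sem)
})

test_that("the spatial process always terminates", {
  set.seed(707)
  sched <- test_schedule(10000)
  sp <- strategy_params(max_steps_per_trial = 10000L)
  ds <- simulate_mixture_dataset(mixture_params(0, 0, 100, 6), sched,
                                 strategy_params = sp, labels = FALSE)
  expect_identical(sum(ds$truncated), 0L)
})

test_that("run_process_until_goal produces labelled complete trials and handles the degenerate start", {
  set.seed(808)
  tr <- run_process_until_goal("spatial", 12, cfg)
  expect_true(is_complete(tr, cfg))
  expect_true(all(tr$strategy_labels == "spatial"))
  expect_identical(tr$visits[length(tr$visits)], cfg$goal_index)
  tr0 <- run_process_until_goal("random", 0, cfg)
  expect_identical(length(tr0$visits), 0L)
  expect_true(is_complete(tr0, cfg))
  # guard: a serial_cw walker in a huge maze cannot reach the goal backwards
  expect_error(
    run_process_until_goal("serial_cw", 1,
                           params = strategy_params(max_steps_per_trial = 5),
                           strict = TRUE),
    "guard")
})

test_that("every generated segment is in the legal +-1..12 range", {
  set.seed(909)
  sched <- test_schedule(300)
  ds <- simulate_mixture_dataset(mixture_params(34, 33, 33, 3), sched)
  for (i in seq_len(length(ds))) {
    seg <- segments_from_visits(ds$start[i], ds$visits[[i]], cfg)
    expect_true(all(abs(seg) >= 1 & abs(seg) <= 12))
  }
})
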