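true_markov <- function() {
  markov_params(c(0.4, 0.1, 0.1, 0.4),
                rbind(c(0.3, 0.3, 0.1, 0.3),
                      c(0.1, 0.6, 0.1, 0.2),
                      c(0.1, 0.1, 0.6, 0.2),
                      c(0.1, 0.2, 0.1, 0.6)))
}

test_that("markov parameters must be row-stochastic", {
  expect_error(markov_params(c(1, 0, 0), diag(4)), "length 4")
  expect_error(markov_params(c(0.5, 0.5, 0, 0.2), diag(4)), "sum to 1")
  m <- diag(4); m[1, 1] <- -1; m[1, 2] <- 2
  expect_error(markov_params(c(1, 0, 0, 0), m), "non-negative")
  p <- true_markov()
  expect_equal(rowSums(p$transitions), rep(1, 4), ignore_attr = TRUE)
})

test_that("row normalization clamps, renormalizes, and falls back to uniform", {
  expect_equal(normalize_rows(matrix(c(0.5, 0.3, -0.1, 0.3), 1)),
               matrix(c(0.5, 0.3, 0, 0.3) / 1.1, 1))
  r <- matrix(c(0.2, 0.3, 0.1, 0.4), 1)
  expect_equal(normalize_rows(r), r)
  expect_equal(normalize_rows(matrix(0, 1, 4)), matrix(0.25, 1, 4))
  set.seed(61)
  m <- matrix(rnorm(20), 5, 4)
  nm <- normalize_rows(m)
  expect_equal(rowSums(nm), rep(1, 5))
  expect_true(all(nm >= 0))
})

test_that("absorbing chains pin the strategy and its direction", {
  set.seed(62)
  sp_only <- markov_params(c(0, 0, 0, 1), diag(4))
  tr <- simulate_markov_trial(sp_only, 12L, cfg)
  expect_true(all(tr$strategy_labels == "spatial"))
  cw_only <- markov_params(c(0, 1, 0, 0), diag(4))
  tr2 <- simulate_markov_trial(cw_only, 12L, cfg)
  expect_true(all(tr2$strategy_labels == "serial_cw"))
  expect_true(all(trial_segments(tr2, cfg) >= 1L))
  ccw_only <- markov_params(c(0, 0, 1, 0), diag(4))
  tr3 <- simulate_markov_trial(ccw_only, 12L, cfg)
  expect_true(all(trial_segments(tr3, cfg) <= -1L))
})

test_that("label transition frequencies reproduce the transition matrix", {
  set.seed(63)
  ds <- simulate_markov_dataset(true_markov(), test_schedule(9000))
  labs <- ds$strategy_labels
  prev <- unlist(lapply(labs, function(l) l[-length(l)]))
  nxt <- unlist(lapply(labs, function(l) l[-1]))
  expect_gt(length(prev), 50000)
  lev <- c("random", "serial_cw", "serial_ccw", "spatial")
  emp <- prop.table(table(factor(prev, lev), factor(nxt, lev)), margin = 1)
  expect_lt(max(abs(emp - true_markov()$transitions)), 0.02)
  first <- vapply(labs[lengths(labs) > 0], `[`, "", 1L)
  emp_init <- prop.table(table(factor(first, lev)))
  expect_lt(max(abs(emp_init - true_markov()$initial)), 0.02)
})

test_that("mutation perturbs within bounds and vanishes in the zero-noise limit", {
  set.seed(64)
  ind <- params_to_matrix_test <- rbind(c(0.25, 0.25, 0.25, 0.25),
                                        matrix(0.25, 4, 4))
  mut <- ga_mutate(ind, 0.1)
  expect_equal(rowSums(mut), rep(1, 5))
  expect_true(all(mut >= 0))
  expect_false(identical(mut, ind))
  expect_equal(ga_mutate(ind, 1e-12), ind, tolerance = 1e-9)
  # uniform(-0.1, 0.1) noise moves an interior element by at most 0.1
  # before renormalization; after renormalizing a uniform row stays close
  expect_lt(max(abs(mut - ind)), 0.25)
})

test_that("crossover takes whole rows from either parent with a fair coin", {
  a <- matrix(1, 5, 4) / 4
  b <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), each = 5), 5, 4)
  expect_identical(ga_crossover(a, a), a)
  set.seed(65)
  n_a <- 0
  for (i in 1:2000) {
    off <- ga_crossover(a, b)
    from_a <- apply(off, 1, function(r) all(r == a[1, ]))
    from_b <- apply(off, 1, function(r) all(r == b[1, ]))
    expect_true(all(from_a | from_b))
    n_a <- n_a + sum(from_a)
  }
  tol <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(n_a / 10000 - 0.5), tol)
})

test_that("elitism under a frozen evaluation seed yields a non-increasing best error", {
  set.seed(66)
  sched <- test_schedule(60)
  target <- simulate_markov_dataset(true_markov(), sched)
  fit <- fit_markov(target, sched, population = 12, generations = 8,
                    elite = 6, freeze_eval = TRUE)
  expect_true(all(diff(fit$error_trace[, 1]) <= 1e-12))
  expect_identical(nrow(fit$error_trace), 8L)
})

test_that("the genetic algorithm validates its configuration", {
  sched <- test_schedule(20)
  set.seed(67)
  target <- simulate_markov_dataset(true_markov(), sched)
  expect_error(fit_markov(target, sched, population = 1), "at least 2")
  expect_error(fit_markov(target, sched, population = 10, elite = 10),
               "elite")
})

test_that("fitted matrices expose standard accessors", {
  set.seed(68)
  sched <- test_schedule(40)
  target <- simulate_markov_dataset(true_markov(), sched)
  fit <- fit_markov(target, sched, population = 8, generations = 3,
                    elite = 4)
  co <- coef(fit)
  expect_identical(dim(co), c(5L, 4L))
  expect_equal(rowSums(co), rep(1, 5), ignore_attr = TRUE)
  sim <- simulate(fit, schedule = sched, seed = 1)
  expect_s3_class(sim, "maze_dataset")
  expect_identical(length(sim), nrow(sched))
})

test_that("generated label sequences are Markov: lag-2 adds nothing beyond lag-1", {
  set.seed(69)
  ds <- simulate_markov_dataset(true_markov(), test_schedule(8000))
  labs <- Filter(function(l) length(l) >= 3, ds$strategy_labels)
  a <- unlist(lapply(labs, function(l) l[seq_len(length(l) - 2)]))
  b <- unlist(lapply(labs, function(l) l[seq(2, length(l) - 1)]))
  cc <- unlist(lapply(labs, function(l) l[seq(3, length(l))]))
  # P(next | prev) vs P(next | prev, prevprev), on the well-populated cells
  lev <- c("random", "serial_cw", "serial_ccw", "spatial")
  p1 <- prop.table(table(factor(b, lev), factor(cc, lev)), 1)
  tab2 <- table(paste(a, b), factor(cc, lev))
  big <- rowSums(tab2) > 2000
  p2 <- prop.table(tab2[big, , drop = FALSE], 1)
  prev_of <- sub("^\\S+ ", "", rownames(p2))
  expect_lt(max(abs(p2 - p1[prev_of, ])), 0.04)
})
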