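test_that("mixture parameters validate the simplex and persistence", {
  expect_error(mixture_params(50, 40, 20), "sum to 100")
  expect_error(mixture_params(-10, 60, 50), "non-negative")
  expect_error(mixture_params(30, 30, 40, 0), "n_persist")
  p <- mixture_params(58.2, 28.4, 13.4, 6)
  expect_equal(p$p_random + p$p_serial + p$p_spatial, 100)
})

test_that("strategy labels change only at persistence-block boundaries", {
  set.seed(31)
  for (N in c(1L, 3L, 6L)) {
    ds <- simulate_mixture_dataset(mixture_params(34, 33, 33, N),
                                   test_schedule(80))
    for (i in seq_len(length(ds))) {
      lab <- ds$strategy_labels[[i]]
      if (length(lab) < 2L) next
      changes <- which(lab[-1] != lab[-length(lab)])  # change before seg j+1
      expect_true(all(changes %% N == 0))
    }
  }
})

test_that("with N = 1 strategy labels are nearly independent across segments", {
  set.seed(32)
  ds <- simulate_mixture_dataset(mixture_params(34, 33, 33, 1),
                                 test_schedule(3000))
  labs <- ds$strategy_labels
  prev <- unlist(lapply(labs, function(l) l[-length(l)]))
  nxt <- unlist(lapply(labs, function(l) l[-1]))
  # lag-1 dependence: max deviation of P(next | prev) from P(next)
  marg <- prop.table(table(nxt))
  conds <- prop.table(table(prev, nxt), margin = 1)
  expect_lt(max(abs(sweep(conds, 2, marg[colnames(conds)]))), 0.05)
})

test_that("degenerate mixtures reduce to their pure process", {
  set.seed(33)
  ds <- simulate_mixture_dataset(mixture_params(0, 0, 100, 6),
                                 test_schedule(2000), labels = FALSE)
  first <- vapply(ds$visits, `[`, 0L, 1L)
  expect_identical(unname(which.max(tabulate(first + 1L, 24))) - 1L, 0L)
})

test_that("the simplex grid enumerates non-negative triples summing to 100", {
  g <- mixture_grid(50)
  expect_identical(nrow(g), 6L)
  expect_true(all(rowSums(g) == 100))
  expect_identical(nrow(mixture_grid(2)), 1326L)
  expect_error(mixture_grid(3), "divisor")
  expect_error(mixture_grid(0), "divisor")
})

test_that("grid fitting is reproducible and self-consistent at a generating grid point", {
  set.seed(34)
  sched <- test_schedule(1900)
  truth <- mixture_params(20, 40, 40, 6)
  target <- simulate_mixture_dataset(truth, sched, labels = FALSE)
  set.seed(35)
  fit <- fit_mixture(target, sched, increment = 20, n_persist = 6,
                     repetitions = 3)
  expect_s3_class(fit, "mixture_fit")
  co <- coef(fit)
  expect_identical(unname(co[["p_random"]]), 20)
  expect_identical(unname(co[["p_serial"]]), 40)
  expect_identical(unname(co[["p_spatial"]]), 40)
  expect_true(all(fit$surface$mse >= 0))
  expect_equal(min(fit$surface$mse), unname(fit$error_by_n["6"]))
  # bit-for-bit reproducibility under the same master seed
  set.seed(35)
  fit2 <- fit_mixture(target, sched, increment = 20, n_persist = 6,
                      repetitions = 3)
  expect_identical(fit$surface, fit2$surface)
})

test_that("recovery error shrinks with schedule size", {
  set.seed(36)
  truth <- mixture_params(20, 40, 40, 4)
  err_for <- function(n) {
    sched <- test_schedule(n)
    target <- simulate_mixture_dataset(truth, sched, labels = FALSE)
    fit <- fit_mixture(target, sched, increment = 10, n_persist = 4,
                       repetitions = 3)
    sum(abs(coef(fit)[1:3] - c(20, 40, 40)))
  }
  expect_lte(err_for(1900), err_for(190) + 10)  # allow grid-step slack
})

test_that("the N scan returns a length-matched profile and honours trivial ranges", {
  set.seed(37)
  sched <- test_schedule(150)
  target <- simulate_mixture_dataset(mixture_params(30, 30, 40, 3), sched,
                                     labels = FALSE)
  fit <- scan_n(target, sched, n_range = 4L, increment = 50,
                repetitions = 2)
  expect_identical(fit$best$n_persist, 4L)
  expect_identical(names(fit$error_by_n), "4")
  fit2 <- scan_n(target, sched, n_range = c(2L, 5L), increment = 50,
                 repetitions = 2)
  expect_identical(length(fit2$error_by_n), 2L)
  expect_true(all(fit2$error_by_n >= 0))
  expect_error(fit_mixture(target, sched, n_persist = integer(0)),
               "at least one")
})

test_that("argmin averaging returns the mean of per-repetition optima", {
  set.seed(38)
  sched <- test_schedule(200)
  target <- simulate_mixture_dataset(mixture_params(30, 30, 40, 6), sched,
                                     labels = FALSE)
  fit <- fit_mixture(target, sched, increment = 25, n_persist = 6,
                     repetitions = 4, average = "argmin")
  co <- coef(fit)
  expect_equal(sum(co[1:3]), 100)
  # the average of grid triples need not sit on the grid
  expect_true(all(co[1:3] >= 0))
})

test_that("schedule structure is preserved in simulated datasets", {
  set.seed(39)
  sched <- data.frame(mouse_id = rep(c("a", "b"), each = 10),
                      day = 1L, trial = rep(1:10, 2),
                      start = rep(c(5L, 12L), each = 10))
  ds <- simulate_mixture_dataset(mixture_params(30, 30, 40, 6), sched)
  expect_identical(length(ds), 20L)
  expect_identical(table(ds$mouse_id), table(sched$mouse_id))
  expect_identical(ds$start, sched$start)
  set.seed(40)
  d1 <- simulate_mixture_dataset(mixture_params(30, 30, 40, 6), sched)
  set.seed(40)
  d2 <- simulate_mixture_dataset(mixture_params(30, 30, 40, 6), sched)
  expect_identical(d1$visits, d2$visits)
})
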