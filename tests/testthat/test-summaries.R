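test_that("a hand-countable single-trial dataset summarizes exactly", {
  ds <- scripted_dataset(22L, list(c(23L, 0L)))
  s <- summarize_dataset(ds, quiet = TRUE)
  expect_equal(unname(s$trial_length[2]), 1)
  expect_equal(sum(s$trial_length), 1)
  expect_equal(unname(s$segment_size[["1"]]), 1)
  expect_equal(unname(s$serial_bout[2]), 1)
  expect_equal(unname(s$vestibule_visits[["23"]]), 0.5)
  expect_equal(unname(s$vestibule_visits[["0"]]), 0.5)
})

test_that("summaries are probability vectors, order-invariant, and pool overflow mass", {
  set.seed(21)
  sched <- test_schedule(300)
  ds <- simulate_mixture_dataset(mixture_params(50, 25, 25, 4), sched)
  s <- summarize_dataset(ds, quiet = TRUE)
  for (comp in s) {
    expect_true(all(comp >= 0))
    expect_equal(sum(comp), 1, tolerance = 1e-9)
  }
  perm <- sample(length(ds))
  ds2 <- subset_dataset(ds, idx = seq_along(perm))
  ds2$mouse_id <- ds$mouse_id[perm]; ds2$day <- ds$day[perm]
  ds2$trial <- ds$trial[perm]; ds2$start <- ds$start[perm]
  ds2$visits <- ds$visits[perm]; ds2$truncated <- ds$truncated[perm]
  expect_equal(unclass(summarize_dataset(ds2, quiet = TRUE)), unclass(s),
               ignore_attr = TRUE)
  # a 40-segment trial lands in the capped top bin, conserving total mass
  long <- scripted_dataset(12L, list(c(rep(c(1L, 2L), 20L), 0L)))
  sl <- summarize_dataset(long, trial_cap = 30L, quiet = TRUE)
  expect_equal(unname(sl$trial_length[30]), 1)
  expect_equal(sum(sl$trial_length), 1)
})

test_that("a large pure-random dataset visits vestibules uniformly", {
  set.seed(22)
  sched <- test_schedule(2000)
  ds <- simulate_mixture_dataset(mixture_params(100, 0, 0, 6), sched,
                                 labels = FALSE)
  s <- summarize_dataset(ds, quiet = TRUE)
  # visits before the last are uniform over non-current vestibules; the goal
  # gains the terminal visit of every trial, so compare non-goal bins only
  counts <- s$vestibule_visits[-1] * sum(lengths(ds$visits))
  gof <- chisq.test(counts, p = rep(1 / 23, 23))
  expect_gt(gof$p.value, 0.001)
})

test_that("mse comparator: identity zero, symmetry, one-hot closed form, shape errors", {
  set.seed(23)
  ds <- simulate_mixture_dataset(mixture_params(40, 30, 30, 6),
                                 test_schedule(50))
  s <- summarize_dataset(ds, quiet = TRUE)
  expect_identical(summary_mse(s, s), 0)
  a <- list(x = c(1, 0, 0, 0))
  b <- list(x = c(0, 0, 1, 0))
  expect_equal(summary_mse(a, b), 2 / 4)   # two displaced one-hot bins
  expect_equal(summary_mse(a, b), summary_mse(b, a))
  expect_error(summary_mse(a, list(x = c(1, 0))), "shapes differ")
  expect_error(summary_mse(a, list(y = 1), components = "x"), "missing")
  expect_gt(summary_mse(a, b), 0)
})

test_that("per-index summaries: one-hot rows for a single trial, empty later rows", {
  ds <- scripted_dataset(5L, list(c(3L, 1L, 0L)))
  pk <- summarize_per_index(ds, K = 10, quiet = TRUE)
  expect_equal(rowSums(pk$segment_size_by_index), c(1, 1, 1, rep(0, 7)),
               ignore_attr = TRUE)
  expect_equal(rowSums(pk$vestibule_by_index), c(1, 1, 1, rep(0, 7)),
               ignore_attr = TRUE)
  expect_equal(unname(pk$vestibule_by_index[1, "3"]), 1)
  expect_equal(unname(pk$segment_size_by_index[1, "-2"]), 1)
})

test_that("per-index rows equal the aggregation of per-trial one-hots", {
  set.seed(24)
  sched <- test_schedule(120)
  ds <- simulate_mixture_dataset(mixture_params(40, 30, 30, 6), sched)
  pk <- summarize_per_index(ds, K = 5, quiet = TRUE)
  for (k in 1:5) {
    rows <- Filter(function(v) length(v) >= k, ds$visits)
    idx <- which(lengths(ds$visits) >= k)
    vest <- vapply(idx, function(i) ds$visits[[i]][k], 0L)
    expect_equal(pk$vestibule_by_index[k, ],
                 tabulate(vest + 1L, 24) / length(vest), ignore_attr = TRUE)
  }
})

test_that("the first spatial-process segment already concentrates near the goal", {
  set.seed(25)
  sched <- test_schedule(2000)
  ds <- simulate_mixture_dataset(mixture_params(0, 0, 100, 6), sched,
                                 labels = FALSE)
  pk <- summarize_per_index(ds, K = 1, quiet = TRUE)
  expect_identical(unname(which.max(pk$vestibule_by_index[1, ])), 1L)  # goal bin
})

test_that("summary export is tidy and complete", {
  ds <- scripted_dataset(22L, list(c(23L, 0L)))
  df <- summary_to_df(summarize_dataset(ds, quiet = TRUE))
  expect_named(df, c("component", "bin", "proportion"))
  expect_identical(nrow(df), 30L + 24L + 24L + 15L)
  expect_equal(sum(df$proportion), 4)
})
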