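#' Read vestibule sequences from CSV
#'
#' Expects columns `mouse_id, day, trial, step_index, vestibule`, with
#' `step_index` 0 holding the start vestibule and subsequent rows the
#' visits in order. Trials whose last vestibule is not the goal are kept
#' but flagged incomplete (summaries exclude them with a message).
#'
#' @param path CSV file path.
#' @param config A [maze_config()].
#' @return A [maze_dataset()].
#' @export
read_sequences <- function(path, config = maze_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "day", "trial", "step_index", "vestibule")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$vestibule) | df$vestibule < 0 |
                 df$vestibule >= config$n_vestibules |
                 df$vestibule != floor(df$vestibule))
  if (length(bad))
    stop("vestibule out of range 0..", config$n_vestibules - 1L,
         " at file row ", bad[1L] + 1L)
  key <- paste(df$mouse_id, df$day, df$trial, sep = "\r")
  df <- df[order(factor(key, levels = unique(key)), df$step_index), ]
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  trials <- lapply(groups, function(rows) {
    si <- df$step_index[rows]
    if (!identical(as.integer(si), seq_along(si) - 1L))
      stop("non-contiguous step_index for trial starting at file row ",
           rows[1L] + 1L)
    list(mouse_id = df$mouse_id[rows[1L]], day = df$day[rows[1L]],
         trial = df$trial[rows[1L]], start = df$vestibule[rows[1L]],
         visits = as.integer(df$vestibule[rows[-1L]]))
  })
  trials <- unname(trials)
  new_maze_dataset(
    vapply(trials, function(x) as.character(x$mouse_id), ""),
    vapply(trials, function(x) as.integer(x$day), 0L),
    vapply(trials, function(x) as.integer(x$trial), 0L),
    vapply(trials, function(x) as.integer(x$start), 0L),
    lapply(trials, `[[`, "visits"),
    metadata = list(source = path), config = config)
}

#' Write vestibule sequences to CSV
#'
#' Inverse of [read_sequences()] (ground-truth strategy labels are not part
#' of the sequence format).
#'
#' @param dataset A [maze_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write summary distributions as tidy CSV
#'
#' @param x A `"summary_set"` or objective list.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  utils::write.csv(summary_to_df(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# small stable polynomial hash over a serialized object, used to stamp
# saved fits with the configuration that produced them
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Save a fit result as JSON
#'
#' Stores the fitted parameters, error landscape/trace, settings, the seed
#' (if supplied) and a hash of the producing configuration, at full numeric
#' precision so that a reload restores the parameters bit-exactly.
#'
#' @param fit A `"mixture_fit"` or `"markov_fit"`.
#' @param path Output JSON path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
save_fit <- function(fit, path, seed = NULL) {
  if (inherits(fit, "mixture_fit")) {
    payload <- list(
      type = "mixture_fit",
      best = unclass(fit$best),
      error_by_n = as.list(fit$error_by_n),
      surface = fit$surface,
      increment = fit$increment, repetitions = fit$repetitions,
      components = fit$components, average = fit$average,
      n_trials = fit$n_trials)
  } else if (inherits(fit, "markov_fit")) {
    payload <- list(
      type = "markov_fit",
      best = list(initial = as.numeric(fit$best$initial),
                  transitions = unname(fit$best$transitions)),
      per_run = lapply(fit$per_run, function(p)
        list(initial = as.numeric(p$initial),
             transitions = unname(p$transitions))),
      error_trace = fit$error_trace,
      best_mse = fit$best_mse, population = fit$population,
      generations = fit$generations, elite = fit$elite,
      components = fit$components, K = fit$K,
      n_trials = fit$n_trials)
  } else stop("fit must be a mixture_fit or markov_fit")
  payload$seed <- seed
  settings <- setdiff(names(payload),
                      c("surface", "error_trace", "error_by_n", "per_run"))
  payload$config_hash <- config_hash(payload[settings])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' Load a saved fit
#'
#' @param path JSON path written by [save_fit()].
#' @return A list mirroring the saved payload, with `best` restored as a
#'   [mixture_params()] or [markov_params()].
#' @export
load_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(payload$type, "mixture_fit")) {
    payload$best <- mixture_params(payload$best$p_random,
                                   payload$best$p_serial,
                                   payload$best$p_spatial,
                                   payload$best$n_persist)
  } else if (identical(payload$type, "markov_fit")) {
    payload$best <- markov_params(payload$best$initial,
                                  payload$best$transitions)
  }
  payload
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level blocks (all optional; absent blocks fall back to
#' package defaults): `maze` (`n_vestibules, goal_index, visit_radius_cm,
#' arena_radius_cm, sample_rate_hz`), `strategies` (`spatial.tau`,
#' `serial.center_cw` etc., `max_steps_per_trial`), `grid` (`increment,
#' n_range, repetitions`), `ga` (`population, generations, elite,
#' mutation_half_range, repetitions`), `classifier` (`spatial_max_visits,
#' serial_min_bout`), `plan` (`n_mice, trials_per_day, days,
#' min_start_distance`), and `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `maze` ([maze_config()]), `strategies`
#'   ([strategy_params()]), `grid`, `ga`, `classifier`, `plan`
#'   ([experiment_plan()]), `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  take <- function(block, f) do.call(f, as.list(raw[[block]] %||% list()))
  sp_block <- raw$strategies %||% list()
  strategies <- strategy_params(
    spatial = do.call(spatial_params, as.list(sp_block$spatial %||% list())),
    serial = do.call(serial_params, as.list(sp_block$serial %||% list())),
    max_steps_per_trial = sp_block$max_steps_per_trial %||% 1000L)
  list(maze = take("maze", maze_config),
       strategies = strategies,
       grid = utils::modifyList(list(increment = 2, n_range = 1:15,
                                     repetitions = 10L),
                                as.list(raw$grid %||% list())),
       ga = utils::modifyList(list(population = 500L, generations = 500L,
                                   elite = 250L, mutation_half_range = 0.1,
                                   repetitions = 10L),
                              as.list(raw$ga %||% list())),
       classifier = utils::modifyList(list(spatial_max_visits = 3L,
                                           serial_min_bout = 3L),
                                      as.list(raw$classifier %||% list())),
       plan = take("plan", experiment_plan),
       seed = raw$seed)
}
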