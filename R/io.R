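# CSV readers/writers for the two interchange schemas (long trial data and
# parameter tables) and the YAML run configuration.

#' Read and validate long-format trial data
#'
#' Reads the trial CSV schema (`participant_id`, `gpts`, `block_index`,
#' `dictator_type`, `trial`, `return_bin`, `hi_rating`, `si_rating`,
#' `order_label`), validates every participant's session (18 trials in 3
#' blocks of 6, recognized dictator types, ratings in 1-100, GPTS in
#' 32-160), and normalizes row order to (participant, block, trial).
#' Violations raise errors naming the offending participant and column.
#'
#' @param path path to a CSV file.
#' @return A validated long trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(TRIAL_COLUMNS, "order_label"), names(df))
  if (length(missing_cols))
    stop("trial file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  sessions <- split_sessions(df)
  out <- do.call(rbind, sessions)
  rownames(out) <- NULL
  out
}

#' Write long-format trial data
#'
#' @param trials a long trial data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter table
#'
#' Reads the parameter CSV schema (`participant_id`, the six parameters,
#' optionally `gpts`, `lp`, `loglik`, `converged`) and validates every row
#' against the parameter invariants.
#'
#' @param path path to a CSV file.
#' @return A parameter-table data frame.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", PARAM_NAMES), names(df))
  if (length(missing_cols))
    stop("parameter file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ as_participant_params(df[i, ]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("invalid parameters for participant ", df$participant_id[i],
           ": ", ok)
  }
  df
}

#' Write a parameter table
#'
#' @param params a parameter-table data frame (attributes such as the full
#'   fit objects are dropped).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

RUN_CONFIG_KEYS <- c("paths", "fit", "population", "pipeline", "seed",
                     "log_level")

#' Run configuration
#'
#' A small container for a reproducible pipeline run: file paths,
#' [fit_config()] overrides, [population_spec()] overrides, pipeline
#' toggles (rating-scoring convention, replay of observed returns), the
#' master seed, and a log level. Round-trips losslessly through YAML;
#' unknown keys are rejected.
#'
#' @param paths named list of file paths.
#' @param fit named list of [fit_config()] argument overrides.
#' @param population named list of [population_spec()] argument overrides.
#' @param pipeline named list of toggles (`score` = "post"/"pre",
#'   `replay` = logical).
#' @param seed master RNG seed.
#' @param log_level one of "quiet", "info", "debug".
#' @return An object of class `run_config`.
#' @export
run_config <- function(paths = list(), fit = list(), population = list(),
                       pipeline = list(score = "post", replay = TRUE),
                       seed = 1L, log_level = "info") {
  if (!log_level %in% c("quiet", "info", "debug"))
    stop("'log_level' must be quiet, info or debug")
  structure(list(paths = paths, fit = fit, population = population,
                 pipeline = pipeline, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path path to a YAML file; unknown top-level keys are rejected.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
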