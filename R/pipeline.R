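# Validation workflow: fit diagnostics, behavioural summaries of
# (simulated) attributions, and parameter-recovery studies.

#' Model-fit diagnostics against the chance floor
#'
#' Recomputes per-trial log-likelihoods at the fitted parameters and
#' aggregates them by trial number, dictator type, and GPTS quantile,
#' comparing every stratum mean with the chance floor `log(1/81)` -- the
#' log-likelihood of a model hedging uniformly over all joint responses.
#'
#' @param param_table fitted parameters, one row per participant (the
#'   [fit_population()] schema).
#' @param trials the long trial data the parameters were fitted to.
#' @param n_quantiles number of GPTS quantile groups.
#' @param config the [fit_config()] used for fitting (scoring convention
#'   and constants).
#' @return An object of class `intent_diagnostics`: per-stratum mean
#'   log-likelihood tables (`by_trial`, `by_dictator`, `by_gpts`), overall
#'   `mean`/`median`/`range`, the `chance_floor` constant, and
#'   `below_floor`, the strata whose mean falls below it.
#' @export
run_diagnostics <- function(param_table, trials, n_quantiles = 4L,
                            config = fit_config()) {
  sessions <- split_sessions(trials)
  ids <- as.character(param_table$participant_id)
  missing_ids <- setdiff(ids, names(sessions))
  if (length(missing_ids) || !all(names(sessions) %in% ids))
    stop("participant ids in the parameter table and trial data do not match")
  cn <- config$constants
  per <- lapply(ids, function(id) {
    sv <- session_vectors(sessions[[id]])
    ll <- cpp_session_loglik(unlist(param_table[match(id, ids), PARAM_NAMES]),
                             sv$r, sv$hi, sv$si, sv$blk,
                             cn$n_pi, cn$p_init, cn$u_init, cn$delta_p, cn$xi,
                             config$score == "post")
    s <- sessions[[id]]
    data.frame(participant_id = id,
               gpts = if ("gpts" %in% names(s)) s$gpts[1] else NA,
               trial_overall = seq_along(ll),
               dictator_type = as.character(s$dictator_type),
               loglik = ll, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, per)
  floor_const <- chance_loglik(cn$n_pi)

  by_trial <- aggregate(loglik ~ trial_overall, long, mean)
  by_dictator <- aggregate(loglik ~ dictator_type, long, mean)
  if (all(is.na(long$gpts))) {
    by_gpts <- data.frame(gpts_group = character(), loglik = numeric())
  } else {
    qs <- unique(stats::quantile(long$gpts, probs = seq(0, 1,
                                                        length.out = n_quantiles + 1),
                                 na.rm = TRUE))
    grp <- cut(long$gpts, breaks = qs, include.lowest = TRUE)
    by_gpts <- aggregate(long$loglik, list(gpts_group = grp), mean)
    names(by_gpts)[2] <- "loglik"
  }
  below <- c(
    if (any(by_trial$loglik < floor_const))
      paste0("trial ", by_trial$trial_overall[by_trial$loglik < floor_const]),
    if (any(by_dictator$loglik < floor_const))
      paste0("dictator ", by_dictator$dictator_type[by_dictator$loglik < floor_const]),
    if (nrow(by_gpts) && any(by_gpts$loglik < floor_const))
      paste0("gpts ", as.character(by_gpts$gpts_group)[by_gpts$loglik < floor_const]))
  structure(list(by_trial = by_trial, by_dictator = by_dictator,
                 by_gpts = by_gpts,
                 mean = mean(long$loglik), median = stats::median(long$loglik),
                 range = range(long$loglik),
                 chance_floor = floor_const,
                 below_floor = below, per_trial_long = long),
            class = "intent_diagnostics")
}

#' @export
print.intent_diagnostics <- function(x, ...) {
  cat("Model-fit diagnostics\n")
  cat(sprintf("  mean per-trial log-likelihood %.3f (median %.3f, range %.2f..%.2f)\n",
              x$mean, x$median, x$range[1], x$range[2]))
  cat(sprintf("  chance floor: %.3f\n", x$chance_floor))
  if (length(x$below_floor))
    cat("  strata below chance:", paste(x$below_floor, collapse = ", "), "\n")
  else cat("  all strata above the chance floor\n")
  invisible(x)
}

# Spearman correlation that degrades to NA (not an error/warning) on
# constant input
spearman_or_na <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Behavioural summary of attributions
#'
#' Descriptive direction-of-effect summary of a long trial data frame:
#' mean harmful-intent and self-interest ratings by dictator type, GPTS
#' group, and trial number; the Spearman correlation between GPTS and each
#' participant's mean rating; and the overall HI-SI correlation. Rank
#' correlations on constant input are reported as `NA`.
#'
#' @param trials long-format trial data.
#' @param n_gpts_groups number of GPTS quantile groups.
#' @return An object of class `attribution_summary`.
#' @export
summarize_attributions <- function(trials, n_gpts_groups = 4L) {
  by_dictator <- aggregate(cbind(hi_rating, si_rating) ~ dictator_type,
                           trials, mean)
  by_trial <- aggregate(cbind(hi_rating, si_rating) ~ trial + dictator_type,
                        trials, mean)
  per_part <- aggregate(cbind(hi_rating, si_rating, gpts) ~ participant_id,
                        trials, mean)
  if (all(is.na(trials$gpts))) {
    by_gpts <- data.frame(gpts_group = character(), hi_rating = numeric(),
                          si_rating = numeric())
    rho_hi <- rho_si <- NA_real_
  } else {
    qs <- unique(stats::quantile(per_part$gpts,
                                 probs = seq(0, 1, length.out = n_gpts_groups + 1),
                                 na.rm = TRUE))
    if (length(qs) > 1L) {
      grp <- cut(per_part$gpts, breaks = qs, include.lowest = TRUE)
      by_gpts <- aggregate(per_part[, c("hi_rating", "si_rating")],
                           list(gpts_group = grp), mean)
    } else {
      by_gpts <- data.frame(gpts_group = "all", hi_rating = mean(per_part$hi_rating),
                            si_rating = mean(per_part$si_rating))
    }
    rho_hi <- spearman_or_na(per_part$gpts, per_part$hi_rating)
    rho_si <- spearman_or_na(per_part$gpts, per_part$si_rating)
  }
  structure(list(by_dictator = by_dictator, by_trial = by_trial,
                 by_gpts = by_gpts,
                 rho_gpts_hi = rho_hi, rho_gpts_si = rho_si,
                 rho_hi_si = spearman_or_na(trials$hi_rating,
                                            trials$si_rating),
                 per_participant = per_part),
            class = "attribution_summary")
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat("Attribution summary\n\nMean ratings by dictator type:\n")
  print(x$by_dictator, row.names = FALSE)
  cat(sprintf("\nSpearman rho GPTS vs mean HI: %s, vs mean SI: %s; HI vs SI: %s\n",
              format(round(x$rho_gpts_hi, 3)), format(round(x$rho_gpts_si, 3)),
              format(round(x$rho_hi_si, 3))))
  invisible(x)
}

#' Parameter-recovery study
#'
#' The standard validity check for a cognitive model: simulate sessions
#' from known parameters, refit them, and quantify agreement per parameter
#' (Spearman rho between true and recovered values, mean bias, RMSE).
#'
#' @param spec a [population_spec()] describing the generating population,
#'   or an existing parameter table.
#' @param config the [fit_config()] used for refitting.
#' @param seed RNG seed for the simulation stage.
#' @param verbose passed to [fit_population()].
#' @return An object of class `recovery_report`: `table` (one row per
#'   parameter with `rho`, `bias`, `rmse`), `n`, `n_failed`, and the
#'   merged true/recovered data in `merged`.
#' @export
run_recovery <- function(spec = population_spec(), config = fit_config(),
                         seed = 1L, verbose = FALSE) {
  truth <- if (inherits(spec, "population_spec")) generate_population(spec)
           else spec
  trials <- simulate_population(truth, seed = seed,
                                constants = config$constants,
                                score = config$score)
  fitted <- fit_population(trials, config, verbose = verbose)
  merged <- merge(truth, fitted[, setdiff(names(fitted), "gpts")],
                  by = "participant_id", suffixes = c("_true", "_fit"))
  tab <- do.call(rbind, lapply(PARAM_NAMES, function(nm) {
    tv <- merged[[paste0(nm, "_true")]]
    rv <- merged[[paste0(nm, "_fit")]]
    data.frame(parameter = nm,
               rho = spearman_or_na(tv, rv),
               bias = mean(rv - tv),
               rmse = sqrt(mean((rv - tv)^2)),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, n = nrow(merged),
                 n_failed = attr(fitted, "n_failed"),
                 merged = merged, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulated participants (%d failed fits)\n",
              x$n, x$n_failed))
  print(transform(x$table, rho = round(rho, 3), bias = round(bias, 3),
                  rmse = round(rmse, 3)), row.names = FALSE)
  invisible(x)
}
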