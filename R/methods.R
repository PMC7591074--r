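# S3 methods for fitted intent_fit objects.

# Run the belief recursion over an observed session and return the scored
# belief grid of every trial (post- or pre-update, per the convention).
belief_trajectory <- function(params, session, constants = policy_constants(),
                              score = c("post", "pre")) {
  params <- as_participant_params(params)
  score <- match.arg(score)
  session <- validate_session(session)
  r <- as.integer(session$return_bin)
  blk <- as.integer(session$block_index)
  policy <- apply_policy_uncertainty(build_policy_template(constants),
                                     params$u_pi, constants)
  block_prior <- build_prior(params, constants)
  out <- vector("list", length(r))
  for (b in unique(blk)) {
    idx <- which(blk == b)
    belief <- block_prior
    for (t in idx) {
      pre <- belief
      belief <- bayes_update(belief, r[t], policy)
      out[[t]] <- if (score == "post") belief else pre
    }
    block_prior <- carry_over_prior(block_prior, belief, params$eta)
  }
  out
}

#' @export
print.intent_fit <- function(x, ...) {
  cat("Intent-attribution model fit (MAP)\n")
  cat("Parameters:\n")
  print(round(unlist(x$params), 4))
  cat(sprintf("log-posterior: %.3f   log-likelihood: %.3f  (chance floor per trial: %.3f)\n",
              x$lp, x$loglik, chance_loglik(x$config$constants$n_pi)))
  cat(sprintf("converged: %s   posterior evaluations: %d\n",
              x$converged, x$n_eval))
  invisible(x)
}

#' @export
summary.intent_fit <- function(object, ...) {
  n_pi <- object$config$constants$n_pi
  structure(list(params = unlist(object$params),
                 lp = object$lp, loglik = object$loglik,
                 per_trial = object$per_trial,
                 mean_trial = mean(object$per_trial),
                 chance = chance_loglik(n_pi),
                 above_chance = mean(object$per_trial > chance_loglik(n_pi)),
                 converged = object$converged),
            class = "summary.intent_fit")
}

#' @export
print.summary.intent_fit <- function(x, ...) {
  cat("Intent-attribution model fit\n\nParameters:\n")
  print(round(x$params, 4))
  cat(sprintf("\nlog-posterior %.3f, log-likelihood %.3f over 18 trials\n",
              x$lp, x$loglik))
  cat(sprintf("mean per-trial log-likelihood %.3f (chance floor %.3f); %.0f%% of trials above chance\n",
              x$mean_trial, x$chance, 100 * x$above_chance))
  invisible(x)
}

#' @export
coef.intent_fit <- function(object, ...) unlist(object$params)

#' @export
logLik.intent_fit <- function(object, ...) {
  structure(object$loglik, df = 6L, nobs = length(object$per_trial),
            class = "logLik")
}

#' Expected attributions under a fitted model
#'
#' Runs the belief recursion over the fitted session and returns, for each
#' trial, the belief-mean harmful-intent and self-interest lattice
#' positions mapped back onto the 1-100 rating scale (continuous bin
#' centres, not resampled draws).
#'
#' @param object an `intent_fit`.
#' @param ... unused.
#' @return A data frame with columns `block_index`, `trial`,
#'   `dictator_type`, `hi_expected`, `si_expected`.
#' @export
predict.intent_fit <- function(object, ...) {
  beliefs <- belief_trajectory(object$params, object$session,
                               object$config$constants, object$config$score)
  n <- object$config$constants$n_pi
  idx <- 0:(n - 1)
  hi <- vapply(beliefs, function(b) sum(rowSums(b) * idx), 0)
  si <- vapply(beliefs, function(b) sum(colSums(b) * idx), 0)
  data.frame(block_index = object$session$block_index,
             trial = object$session$trial,
             dictator_type = object$session$dictator_type,
             hi_expected = (hi + 0.5) * 100 / n,
             si_expected = (si + 0.5) * 100 / n)
}

#' @export
residuals.intent_fit <- function(object, ...) {
  pred <- predict(object)
  cbind(hi = object$session$hi_rating - pred$hi_expected,
        si = object$session$si_rating - pred$si_expected)
}

#' Simulate sessions from a fitted model
#'
#' Forward-simulates `nsim` fresh sessions at the fitted parameters. By
#' default the observed return sequences are replayed (so simulated
#' attributions are directly comparable with the fitted data); set
#' `replay = FALSE` to draw fresh dictator behaviour.
#'
#' @param object an `intent_fit`.
#' @param nsim number of sessions.
#' @param seed RNG seed.
#' @param replay replay the fitted session's observed returns.
#' @param ... unused.
#' @return A long trial data frame (`nsim` stacked sessions).
#' @export
simulate.intent_fit <- function(object, nsim = 1, seed = 1L, replay = TRUE,
                                ...) {
  sess <- object$session
  ord <- unique(as.character(sess$dictator_type))
  returns <- if (replay)
    split(as.integer(sess$return_bin), sess$block_index) else NULL
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  out <- lapply(seq_len(nsim), function(i)
    simulate_participant(object$params, order = ord, seed = seeds[i],
                         id = paste0("sim", i),
                         gpts = if ("gpts" %in% names(sess)) sess$gpts[1] else NA,
                         returns = returns,
                         constants = object$config$constants,
                         score = object$config$score))
  do.call(rbind, out)
}

#' Plot per-trial log-likelihoods of a fit
#'
#' Per-trial log-likelihood against trial number, with the chance floor
#' (`log(1/81)` for the default lattice) drawn as a dashed reference line
#' and points keyed by dictator type.
#'
#' @param x an `intent_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.intent_fit <- function(x, ...) {
  n_pi <- x$config$constants$n_pi
  type_col <- setNames(seq_along(DICTATOR_TYPES) + 1, DICTATOR_TYPES)
  cols <- type_col[as.character(x$session$dictator_type)]
  graphics::plot(seq_along(x$per_trial), x$per_trial,
                 xlab = "trial", ylab = "log-likelihood",
                 pch = 19, col = cols,
                 ylim = range(c(x$per_trial, chance_loglik(n_pi))), ...)
  graphics::abline(h = chance_loglik(n_pi), lty = 2)
  graphics::legend("bottomleft", legend = names(type_col), col = type_col,
                   pch = 19, bty = "n")
  invisible(x)
}
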