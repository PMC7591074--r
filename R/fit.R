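# MAP fitting of the six participant parameters: a coarse factorial grid
# scan of the log-posterior seeds a small number of local ascents on a
# transformed (unconstrained) scale.

#' Fitting configuration
#'
#' Collects everything the MAP fitting routine needs: the coarse grid of
#' candidate values per parameter, box bounds, the number of local-ascent
#' restarts taken from the best grid seeds, optimizer controls, the
#' regularizing-prior scale, and the rating-scoring convention.
#'
#' The defaults scan 5 values per parameter (a 15,625-point factorial
#' grid), with the three uncertainty scales spaced geometrically across
#' their bounds, and refine the best 3 seeds by BFGS ascent on the
#' log-posterior.
#'
#' @param pHI0_grid,pSI0_grid grid values for the prior modes.
#' @param uHI0_grid,uSI0_grid,u_pi_grid grid values for the uncertainty
#'   scales (searched on a log scale by default).
#' @param eta_grid grid values for the learning rate.
#' @param bounds named list of length-2 numeric bounds per parameter.
#' @param n_restarts number of grid seeds refined by local ascent.
#' @param maxit maximum BFGS iterations per restart.
#' @param reltol relative convergence tolerance for the ascent.
#' @param prior_sdlog standard deviation of the log-normal regularizer on
#'   the three uncertainty scales.
#' @param score rating-scoring convention, see [session_loglik()].
#' @param constants a [policy_constants()] object.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(pHI0_grid = seq(0.05, 0.95, length.out = 5),
                       uHI0_grid = exp(seq(log(0.05), log(20), length.out = 5)),
                       pSI0_grid = pHI0_grid,
                       uSI0_grid = uHI0_grid,
                       u_pi_grid = uHI0_grid,
                       eta_grid = seq(0, 1, length.out = 5),
                       bounds = list(pHI0 = c(0.01, 0.99),
                                     uHI0 = c(0.05, 20),
                                     pSI0 = c(0.01, 0.99),
                                     uSI0 = c(0.05, 20),
                                     u_pi = c(0.05, 20),
                                     eta = c(0, 1)),
                       n_restarts = 3L,
                       maxit = 100L,
                       reltol = 1e-8,
                       prior_sdlog = 1.5,
                       score = c("post", "pre"),
                       constants = policy_constants()) {
  score <- match.arg(score)
  grids <- list(pHI0 = pHI0_grid, uHI0 = uHI0_grid, pSI0 = pSI0_grid,
                uSI0 = uSI0_grid, u_pi = u_pi_grid, eta = eta_grid)
  if (any(lengths(grids) == 0L)) stop("every parameter grid must be non-empty")
  if (!all(PARAM_NAMES %in% names(bounds)))
    stop("'bounds' must name all of: ", paste(PARAM_NAMES, collapse = ", "))
  for (nm in PARAM_NAMES) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds for ", nm, " must be two finite increasing numbers")
  }
  if (n_restarts < 1L) stop("'n_restarts' must be at least 1")
  if (reltol <= 0) stop("'reltol' must be positive")
  structure(list(grids = grids, bounds = bounds,
                 n_restarts = as.integer(n_restarts),
                 maxit = as.integer(maxit), reltol = reltol,
                 prior_sdlog = prior_sdlog, score = score,
                 constants = constants),
            class = "fit_config")
}

#' Weak regularizing log-prior over participant parameters
#'
#' Uniform within the configured bounds for the prior modes and the
#' learning rate, and log-normal(0, `prior_sdlog`) for the three
#' uncertainty scales (a soft pull towards order-1 values). Returns `-Inf`
#' outside the bounds. The log-normal is not renormalized for the
#' truncation to the bounds (a constant shift, irrelevant to MAP).
#'
#' @param params a [participant_params()] object (or coercible named
#'   vector; values outside the parameter domain score `-Inf` rather than
#'   erroring, so optimizers can probe freely).
#' @param config a [fit_config()] object.
#' @return A single log-density value (possibly `-Inf`).
#' @export
log_prior <- function(params, config = fit_config()) {
  x <- if (inherits(params, "participant_params")) unlist(params)
       else unlist(params)[PARAM_NAMES]
  if (anyNA(x)) stop("missing parameter values")
  b <- config$bounds
  for (nm in PARAM_NAMES)
    if (x[[nm]] < b[[nm]][1] || x[[nm]] > b[[nm]][2]) return(-Inf)
  lp <- 0
  for (nm in c("pHI0", "pSI0", "eta"))
    lp <- lp - log(diff(b[[nm]]))
  for (nm in c("uHI0", "uSI0", "u_pi"))
    lp <- lp + stats::dlnorm(x[[nm]], 0, config$prior_sdlog, log = TRUE)
  unname(lp)
}

# log-prior evaluated on the columns of a data frame of in-bounds params
log_prior_vec <- function(df, config) {
  lp <- rep(-sum(log(vapply(config$bounds[c("pHI0", "pSI0", "eta")], diff, 0))),
            nrow(df))
  for (nm in c("uHI0", "uSI0", "u_pi"))
    lp <- lp + stats::dlnorm(df[[nm]], 0, config$prior_sdlog, log = TRUE)
  lp
}

# extract the integer trial vectors the engine needs
session_vectors <- function(session) {
  session <- validate_session(session)
  list(r = as.integer(session$return_bin),
       hi = rating_to_bin(session$hi_rating),
       si = rating_to_bin(session$si_rating),
       blk = as.integer(session$block_index))
}

#' Coarse grid scan of the log-posterior
#'
#' Evaluates the log-posterior (session log-likelihood plus regularizing
#' log-prior) at every point of the factorial grid in `config` and returns
#' the best `k` points as seeds for local ascent. Ties are broken
#' deterministically by lexicographic parameter order
#' (pHI0, uHI0, pSI0, uSI0, u_pi, eta).
#'
#' @param session one participant's trials.
#' @param config a [fit_config()] object.
#' @param k number of seeds to return (capped at the grid size).
#' @return A data frame of `k` rows: the six parameters, `loglik` and `lp`,
#'   sorted by decreasing `lp`.
#' @export
grid_search <- function(session, config = fit_config(),
                        k = config$n_restarts) {
  sv <- session_vectors(session)
  g <- config$grids
  cn <- config$constants
  ll <- cpp_grid_loglik(g$pHI0, g$uHI0, g$pSI0, g$uSI0, g$u_pi, g$eta,
                        sv$r, sv$hi, sv$si, sv$blk,
                        cn$n_pi, cn$p_init, cn$u_init, cn$delta_p, cn$xi,
                        config$score == "post")
  # expand.grid varies its first argument fastest; this matches the
  # engine's nesting (u_pi slowest ... eta fastest)
  combos <- expand.grid(eta = g$eta, uSI0 = g$uSI0, pSI0 = g$pSI0,
                        uHI0 = g$uHI0, pHI0 = g$pHI0, u_pi = g$u_pi,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, PARAM_NAMES]
  combos$loglik <- ll
  combos$lp <- ll + log_prior_vec(combos, config)
  ord <- order(-combos$lp, combos$pHI0, combos$uHI0, combos$pSI0,
               combos$uSI0, combos$u_pi, combos$eta)
  k <- min(as.integer(k), nrow(combos))
  out <- combos[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- bound-respecting transforms -------------------------------------------
# pHI0/pSI0: scaled logit on their bounds; uncertainty scales: scaled logit
# on the log of their bounds; eta: scaled logit on [0, 1]. The optimizer
# works on the unconstrained theta scale.

theta_from_params <- function(x, bounds) {
  tr <- function(v, lo, hi) {
    f <- (v - lo) / (hi - lo)
    f <- pmin(pmax(f, 1e-8), 1 - 1e-8)
    stats::qlogis(f)
  }
  c(tr(x[["pHI0"]], bounds$pHI0[1], bounds$pHI0[2]),
    tr(log(x[["uHI0"]]), log(bounds$uHI0[1]), log(bounds$uHI0[2])),
    tr(x[["pSI0"]], bounds$pSI0[1], bounds$pSI0[2]),
    tr(log(x[["uSI0"]]), log(bounds$uSI0[1]), log(bounds$uSI0[2])),
    tr(log(x[["u_pi"]]), log(bounds$u_pi[1]), log(bounds$u_pi[2])),
    tr(x[["eta"]], bounds$eta[1], bounds$eta[2]))
}

params_from_theta <- function(theta, bounds) {
  inv <- function(t, lo, hi) lo + (hi - lo) * stats::plogis(t)
  c(pHI0 = inv(theta[1], bounds$pHI0[1], bounds$pHI0[2]),
    uHI0 = exp(inv(theta[2], log(bounds$uHI0[1]), log(bounds$uHI0[2]))),
    pSI0 = inv(theta[3], bounds$pSI0[1], bounds$pSI0[2]),
    uSI0 = exp(inv(theta[4], log(bounds$uSI0[1]), log(bounds$uSI0[2]))),
    u_pi = exp(inv(theta[5], log(bounds$u_pi[1]), log(bounds$u_pi[2]))),
    eta = inv(theta[6], bounds$eta[1], bounds$eta[2]))
}

#' Fit the intent-attribution model to one participant
#'
#' Maximum a posteriori estimation of the six participant parameters: the
#' log-posterior (session log-likelihood plus the weak regularizing prior)
#' is scanned on the coarse factorial grid, and the best `n_restarts` grid
#' points each seed a BFGS ascent on a transformed, unconstrained scale.
#' The returned optimum is guaranteed not to fall below the best grid seed.
#'
#' @param session one participant's 18 trials (see [validate_session()]).
#' @param config a [fit_config()] object.
#' @return An object of class `intent_fit` with components `params` (a
#'   [participant_params()]), `lp`, `loglik`, `per_trial` (length-18
#'   log-likelihood vector), `converged`, `n_eval`, `seeds`, plus the data
#'   and configuration. Supports `print`, `summary`, `coef`, `logLik`,
#'   `predict`, `residuals`, `simulate` and `plot`.
#' @examples
#' \donttest{
#' pars <- participant_params(0.3, 1, 0.6, 1, 1, 0.5)
#' sess <- simulate_participant(pars, seed = 1)
#' fit <- fit_intent(sess)
#' coef(fit)
#' }
#' @export
fit_intent <- function(session, config = fit_config()) {
  session <- validate_session(session)
  sv <- session_vectors(session)
  cn <- config$constants
  score_post <- config$score == "post"
  n_eval <- 0L

  logt <- cpp_log_template(cn$n_pi, cn$p_init, cn$u_init, cn$delta_p)
  loglik_fn <- function(x) {
    cpp_session_total(x, logt, sv$r, sv$hi, sv$si, sv$blk,
                      cn$n_pi, cn$xi, score_post)
  }
  neg_lp <- function(theta) {
    n_eval <<- n_eval + 1L
    x <- params_from_theta(theta, config$bounds)
    -(loglik_fn(x) + log_prior(x, config))
  }

  seeds <- grid_search(session, config, k = config$n_restarts)
  n_eval <- n_eval + prod(lengths(config$grids))

  best <- list(lp = -Inf, x = NULL, converged = FALSE)
  for (s in seq_len(nrow(seeds))) {
    x0 <- unlist(seeds[s, PARAM_NAMES])
    # grid seed itself is a candidate (ascent can only improve on it)
    if (seeds$lp[s] > best$lp)
      best <- list(lp = seeds$lp[s], x = x0, converged = FALSE)
    theta0 <- theta_from_params(x0, config$bounds)
    opt <- tryCatch(
      stats::optim(theta0, neg_lp, method = "BFGS",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    x1 <- params_from_theta(opt$par, config$bounds)
    lp1 <- -opt$value
    if (lp1 > best$lp)
      best <- list(lp = lp1, x = x1, converged = opt$convergence == 0L)
  }
  if (is.null(best$x)) stop("all ascent restarts failed")

  params <- as_participant_params(best$x)
  per_trial <- cpp_session_loglik(unlist(params), sv$r, sv$hi, sv$si, sv$blk,
                                  cn$n_pi, cn$p_init, cn$u_init, cn$delta_p,
                                  cn$xi, score_post)
  loglik <- sum(per_trial)
  structure(list(params = params,
                 lp = loglik + log_prior(params, config),
                 loglik = loglik,
                 per_trial = per_trial,
                 converged = best$converged,
                 n_eval = n_eval,
                 seeds = seeds,
                 session = session,
                 config = config,
                 call = match.call()),
            class = "intent_fit")
}

#' Fit every participant in a long trial data frame
#'
#' Applies [fit_intent()] to each participant and collects the fitted
#' parameters into one table (the parameter-table interchange schema).
#' Participants whose fit errors are dropped with a message and counted in
#' the `n_failed` attribute.
#'
#' @param trials long-format trial data with a `participant_id` column.
#' @param config a [fit_config()] object.
#' @param verbose print progress every 50 participants.
#' @return A data frame with one row per participant: `participant_id`,
#'   `gpts`, the six parameters, `lp`, `loglik`, `converged`, `n_eval`;
#'   the full `intent_fit` objects in attribute `"fits"`.
#' @export
fit_population <- function(trials, config = fit_config(), verbose = FALSE) {
  sessions <- split_sessions(trials)
  rows <- vector("list", length(sessions))
  fits <- vector("list", length(sessions))
  failed <- 0L
  for (i in seq_along(sessions)) {
    id <- names(sessions)[i]
    f <- tryCatch(fit_intent(sessions[[i]], config), error = function(e) {
      message("fit failed for participant ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(f)) { failed <- failed + 1L; next }
    fits[[i]] <- f
    g <- if ("gpts" %in% names(sessions[[i]])) sessions[[i]]$gpts[1] else NA
    rows[[i]] <- data.frame(participant_id = id, gpts = g,
                            as.list(unlist(f$params)),
                            lp = f$lp, loglik = f$loglik,
                            converged = f$converged, n_eval = f$n_eval,
                            stringsAsFactors = FALSE)
    if (verbose && i %% 50L == 0L)
      message("fitted ", i, "/", length(sessions), " participants")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "fits") <- fits[!vapply(fits, is.null, TRUE)]
  attr(out, "n_failed") <- failed
  out
}
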