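# Synthetic pseudo-populations: parameter tables with the statistical
# structure the downstream analysis assumes (right-skewed paranoia scores
# and paranoia-coupled latent parameters), so every stage is testable
# without the original behavioural dataset.

#' Specification of a synthetic population
#'
#' Describes how pseudo-participants are drawn: a right-skewed GPTS
#' marginal (`32 + 128 * Beta(shape1, shape2)`, rounded), and for each of
#' the six parameters a linear model on the z-scored GPTS at the link
#' scale -- logit for `pHI0`, `pSI0`, `eta`; log for `uHI0`, `uSI0`,
#' `u_pi` -- with Gaussian noise, clipped to the fitting bounds.
#'
#' The default couplings put paranoia positively on policy uncertainty
#' (+0.09 per GPTS z on log `u_pi`), weakly on the two prior uncertainties
#' (+0.04 and +0.03), on the harmful-intent prior mode (+0.35 on the logit),
#' and leave the learning rate uncoupled.
#'
#' @param n number of pseudo-participants.
#' @param gpts_shape1,gpts_shape2 Beta shape parameters of the GPTS
#'   marginal.
#' @param intercepts named link-scale intercepts for the six parameters.
#' @param couplings named link-scale slopes on z-scored GPTS.
#' @param noise named link-scale Gaussian noise standard deviations.
#' @param bounds named list of per-parameter bounds for clipping (the
#'   fitting bounds by default).
#' @param seed RNG seed used by [generate_population()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 200L,
                            gpts_shape1 = 1.2, gpts_shape2 = 4,
                            intercepts = c(pHI0 = qlogis(0.3), uHI0 = 0,
                                           pSI0 = qlogis(0.6), uSI0 = 0,
                                           u_pi = 0, eta = 0),
                            couplings = c(pHI0 = 0.35, uHI0 = 0.04,
                                          pSI0 = 0, uSI0 = 0.03,
                                          u_pi = 0.09, eta = 0),
                            noise = c(pHI0 = 1.0, uHI0 = 0.3,
                                      pSI0 = 1.0, uSI0 = 0.3,
                                      u_pi = 0.3, eta = 0.75),
                            bounds = fit_config()$bounds,
                            seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  for (v in list(intercepts, couplings, noise))
    if (!all(PARAM_NAMES %in% names(v)))
      stop("intercepts, couplings and noise must name all six parameters")
  if (any(noise < 0)) stop("noise scales must be non-negative")
  structure(list(n = n, gpts_shape1 = gpts_shape1, gpts_shape2 = gpts_shape2,
                 intercepts = intercepts[PARAM_NAMES],
                 couplings = couplings[PARAM_NAMES],
                 noise = noise[PARAM_NAMES],
                 bounds = bounds, seed = as.integer(seed)),
            class = "population_spec")
}

# clip to the open interior of a bound by a hair so participant_params
# invariants (strict positivity / open unit interval) always hold
clip_bounds <- function(x, b) pmin(pmax(x, b[1]), b[2])

#' Generate a synthetic parameter table
#'
#' Draws GPTS totals from the spec's marginal, z-scores them, maps them
#' through the link-scale linear models with Gaussian noise, and clips to
#' the fitting bounds. Deterministic given the spec's seed.
#'
#' @param spec a [population_spec()] object.
#' @return A data frame of `spec$n` rows: `participant_id`, `gpts`, and the
#'   six parameters, each row satisfying the parameter invariants.
#' @export
generate_population <- function(spec = population_spec()) {
  if (!inherits(spec, "population_spec")) stop("'spec' must be a population_spec")
  set.seed(spec$seed)
  n <- spec$n
  gpts <- as.integer(32 + round(128 * stats::rbeta(n, spec$gpts_shape1,
                                                   spec$gpts_shape2)))
  z <- if (n > 1L && stats::sd(gpts) > 0) (gpts - mean(gpts)) / stats::sd(gpts)
       else rep(0, n)
  link <- function(nm) spec$intercepts[[nm]] + spec$couplings[[nm]] * z +
    spec$noise[[nm]] * stats::rnorm(n)
  logit_params <- c("pHI0", "pSI0", "eta")
  out <- data.frame(participant_id = sprintf("p%04d", seq_len(n)),
                    gpts = gpts, stringsAsFactors = FALSE)
  for (nm in PARAM_NAMES) {
    eta_lin <- link(nm)
    val <- if (nm %in% logit_params) stats::plogis(eta_lin) else exp(eta_lin)
    val <- clip_bounds(val, spec$bounds[[nm]])
    if (spec$noise[[nm]] == 0 && spec$couplings[[nm]] == 0 &&
        (all(val == spec$bounds[[nm]][1]) || all(val == spec$bounds[[nm]][2])))
      warning("degenerate spec: parameter ", nm,
              " is pinned at a bound with zero noise and zero coupling")
    out[[nm]] <- val
  }
  out
}

# printed pHI0/pSI0 ranges of the three density clusters used for the
# network-artefact control
CLUSTER_RANGES <- list(
  low    = list(pHI0 = c(0.01, 0.20), pSI0 = c(0.01, 0.20)),
  medium = list(pHI0 = c(0.25, 0.50), pSI0 = c(0.50, 0.75)),
  high   = list(pHI0 = c(0.01, 0.98), pSI0 = c(0.80, 0.98))
)

#' Generate a cluster population for the network-artefact control
#'
#' Samples `pHI0` and `pSI0` uniformly within the named density cluster's
#' ranges (low: both in 0.01-0.2; medium: 0.25-0.5 and 0.5-0.75; high:
#' 0.01-0.98 and 0.8-0.98) and the remaining four parameters from a single
#' shared dense range (log-uniform on 0.25-4 for the three uncertainty
#' scales, uniform on 0.05-0.95 for the learning rate), with no coupling
#' between any of them. Networks fitted to data simulated from such
#' deliberately unstructured clusters reveal which edges model fitting
#' alone can manufacture.
#'
#' @param cluster `"low"`, `"medium"` or `"high"`.
#' @param n number of pseudo-participants (200 in the control recipe).
#' @param seed RNG seed.
#' @return A parameter-table data frame (with an uncoupled GPTS column for
#'   schema completeness).
#' @export
generate_cluster_population <- function(cluster = c("low", "medium", "high"),
                                        n = 200L, seed = 1L) {
  cluster <- match.arg(cluster)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  rg <- CLUSTER_RANGES[[cluster]]
  set.seed(seed)
  data.frame(
    participant_id = sprintf("%s%04d", substr(cluster, 1, 1), seq_len(n)),
    gpts = as.integer(32 + round(128 * stats::rbeta(n, 1.2, 4))),
    pHI0 = stats::runif(n, rg$pHI0[1], rg$pHI0[2]),
    uHI0 = exp(stats::runif(n, log(0.25), log(4))),
    pSI0 = stats::runif(n, rg$pSI0[1], rg$pSI0[2]),
    uSI0 = exp(stats::runif(n, log(0.25), log(4))),
    u_pi = exp(stats::runif(n, log(0.25), log(4))),
    eta = stats::runif(n, 0.05, 0.95),
    stringsAsFactors = FALSE)
}
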