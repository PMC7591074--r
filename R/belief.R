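# Belief grids and the dictator policy map.
#
# A belief grid is a 9x9 matrix of probabilities over the (HI, SI) attribute
# lattice, rows indexed by harmful-intent level 0..8 and columns by
# self-interest level 0..8 (index 0 = totally altruistic end, 8 = totally
# antisocial end). A policy matrix is a 9x9x9 array whose [hi, si, r] entry
# is the probability that a dictator with attributes (hi, si) returns bin r
# (r = 1 means 0% returned, r = 9 means 100%, r = 5 half).

new_belief_grid <- function(m) {
  structure(m, class = "belief_grid")
}

validate_belief_grid <- function(b) {
  if (!is.matrix(b) || !all(dim(b) == dim(b)[1]))
    stop("a belief grid must be a square matrix")
  if (any(b < 0)) stop("belief grid entries must be non-negative")
  if (abs(sum(b) - 1) > 1e-9) stop("belief grid must sum to 1")
  invisible(b)
}

#' Uniform belief grid
#'
#' The maximally uncertain belief: equal mass `1 / n_pi^2` on every lattice
#' cell.
#'
#' @param constants a [policy_constants()] object.
#' @return A `belief_grid` matrix.
#' @export
uniform_belief <- function(constants = policy_constants()) {
  n <- constants$n_pi
  new_belief_grid(matrix(1 / n^2, n, n))
}

#' Initial belief grid from participant parameters
#'
#' Builds the prior joint belief over the attribute lattice as the outer
#' product of two independent sharpened-binomial marginals: the
#' harmful-intent marginal uses mode parameter `pHI0` and exponent
#' `1 / uHI0`, the self-interest marginal uses `pSI0` and `1 / uSI0`.
#' Larger prior uncertainties therefore yield flatter marginals (reduced
#' confidence); in the limit of infinite uncertainty the grid tends to
#' uniform.
#'
#' @param params a [participant_params()] object.
#' @param constants a [policy_constants()] object.
#' @return A `belief_grid` matrix (rows: HI level 0..8, cols: SI level 0..8).
#' @export
build_prior <- function(params, constants = policy_constants()) {
  params <- as_participant_params(params)
  n <- constants$n_pi
  hi <- sharpened_binomial(params$pHI0, 1 / params$uHI0, n - 1)
  si <- sharpened_binomial(params$pSI0, 1 / params$uSI0, n - 1)
  joint <- outer(hi, si)
  new_belief_grid(joint / sum(joint))
}

#' Raw dictator policy template
#'
#' For each attribute level a in 0..(n-1), the marginal return preference is
#' a sharpened binomial over return bins with success probability
#' `1 - p_init - delta_p * a` and exponent `u_init - 2 * delta_p * (a + 1)`.
#' The joint template for a cell (hi, si) is the normalized product of the
#' two marginals. A fully altruistic dictator (hi = 0, si = 0) prefers
#' returning everything (mode at r = 9); a fully antisocial one
#' (hi = 8, si = 8) prefers returning nothing (mode at r = 1).
#'
#' @param constants a [policy_constants()] object.
#' @return A `policy_matrix` array of dim `c(n, n, n)` indexed (HI, SI, r),
#'   with attribute `stage = "raw_template"`.
#' @export
build_policy_template <- function(constants = policy_constants()) {
  n <- constants$n_pi
  marg <- matrix(0, n, n)  # rows: attribute level, cols: return bin
  for (a in 0:(n - 1)) {
    p_a <- 1 - constants$p_init - constants$delta_p * a
    u_a <- constants$u_init - 2 * constants$delta_p * (a + 1)
    if (u_a <= 0)
      stop("policy template exponent non-positive at attribute level ", a,
           "; constants are inconsistent")
    marg[a + 1, ] <- sharpened_binomial(p_a, u_a, n - 1)
  }
  pol <- array(0, c(n, n, n))
  for (i in 1:n) {
    for (j in 1:n) {
      row <- marg[i, ] * marg[j, ]
      pol[i, j, ] <- row / sum(row)
    }
  }
  structure(pol, stage = "raw_template", class = "policy_matrix")
}

#' Apply policy uncertainty and lapse to the template
#'
#' Each row of the raw template is flattened by the participant's policy
#' uncertainty -- raised elementwise to the power `1 / u_pi` -- then a small
#' fixed lapse `xi` is added before renormalization. Larger `u_pi` moves
#' every row towards uniform, making each observed return less informative
#' about the dictator's attributes; the lapse guarantees every return bin
#' keeps strictly positive probability so that Bayesian updates never
#' degenerate.
#'
#' @param template a raw `policy_matrix` from [build_policy_template()].
#' @param u_pi policy uncertainty, strictly positive.
#' @param constants a [policy_constants()] object.
#' @return A `policy_matrix` with attribute `stage = "uncertainty_applied"`.
#' @export
apply_policy_uncertainty <- function(template, u_pi,
                                     constants = policy_constants()) {
  if (!inherits(template, "policy_matrix") ||
      !identical(attr(template, "stage"), "raw_template"))
    stop("'template' must be a raw policy template")
  if (length(u_pi) != 1L || !is.finite(u_pi) || u_pi <= 0)
    stop("'u_pi' must be a single strictly positive number")
  n <- constants$n_pi
  out <- array(0, c(n, n, n))
  for (i in 1:n) {
    for (j in 1:n) {
      w <- template[i, j, ]^(1 / u_pi) + constants$xi
      out[i, j, ] <- w / sum(w)
    }
  }
  structure(out, stage = "uncertainty_applied", class = "policy_matrix")
}

#' @export
print.policy_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Policy matrix (%d x %d attribute cells, %d return bins), stage: %s\n",
              d[1], d[2], d[3], attr(x, "stage")))
  invisible(x)
}

#' Bayesian belief update from one observed return
#'
#' Multiplies the current belief cellwise by the policy likelihood of the
#' observed return bin and renormalizes: the exact posterior over the
#' attribute lattice.
#'
#' @param belief a `belief_grid`.
#' @param observed observed return bin, an integer in `1:n_pi`.
#' @param policy an uncertainty-applied `policy_matrix`.
#' @return The posterior `belief_grid`.
#' @export
bayes_update <- function(belief, observed, policy) {
  if (!inherits(policy, "policy_matrix") ||
      !identical(attr(policy, "stage"), "uncertainty_applied"))
    stop("'policy' must have policy uncertainty applied before updating")
  n <- dim(policy)[3]
  if (length(observed) != 1L || is.na(observed) ||
      observed != as.integer(observed) || observed < 1 || observed > n)
    stop("'observed' must be a single return bin in 1..", n)
  post <- unclass(belief) * policy[, , observed]
  z <- sum(post)
  if (!is.finite(z) || z <= 0)
    stop("belief update produced a zero normalizer")
  new_belief_grid(post / z)
}

#' Carry beliefs over to the next dictator
#'
#' The prior for the next dictator is a convex mixture of the prior the
#' participant held at the start of the current dictator block and the
#' posterior reached at its end, weighted by the learning rate:
#' `(1 - eta) * prior + eta * posterior`. With `eta = 0` nothing learned
#' about one dictator transfers to the next; with `eta = 1` the posterior
#' is adopted wholesale.
#'
#' @param prior_d belief at the start of the completed dictator block.
#' @param posterior_d belief after the block's final update.
#' @param eta learning rate in [0, 1].
#' @return The next block's prior `belief_grid`.
#' @export
carry_over_prior <- function(prior_d, posterior_d, eta) {
  if (length(eta) != 1L || !is.finite(eta) || eta < 0 || eta > 1)
    stop("'eta' must be a single number in [0, 1]")
  m <- (1 - eta) * unclass(prior_d) + eta * unclass(posterior_d)
  new_belief_grid(m / sum(m))
}

#' Map a 1-100 rating onto the 9-level attribute lattice
#'
#' Ratings are collapsed into nine equal-width bins:
#' `min(8, floor(rating * 9 / 100))`. The midpoint rating 50 lands in the
#' middle bin (index 4).
#'
#' @param rating integer rating(s) between 1 and 100.
#' @return Integer lattice indices in 0..8.
#' @seealso [bin_to_rating()]
#' @export
rating_to_bin <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 100))
    stop("ratings must lie between 1 and 100")
  as.integer(pmin(8, floor(rating * 9 / 100)))
}

#' Map a lattice index back to the 1-100 rating scale
#'
#' Inverse of [rating_to_bin()], using bin centres:
#' `round((index + 0.5) * 100 / 9)`.
#'
#' @param index integer lattice indices in 0..8.
#' @return Integer ratings between 1 and 100.
#' @export
bin_to_rating <- function(index) {
  if (any(!is.finite(index)) || any(index < 0) || any(index > 8))
    stop("lattice indices must lie in 0..8")
  as.integer(round((index + 0.5) * 100 / 9))
}

#' Log-likelihood of one trial's reported attributions
#'
#' Reported attributions are modelled as a joint draw of one (HI, SI) cell
#' from the participant's belief grid, so the trial log-likelihood is the
#' log of the probability mass on the reported cell. Under a uniform 9x9
#' belief this is `log(1/81) = -4.394`, the chance floor. Cell mass is
#' floored at 1e-30 before taking the log.
#'
#' @param belief a `belief_grid`.
#' @param hi,si reported lattice indices in 0..8.
#' @return A single log-probability.
#' @export
trial_loglik <- function(belief, hi, si) {
  if (length(hi) != 1L || length(si) != 1L || hi < 0 || hi > 8 || si < 0 || si > 8)
    stop("'hi' and 'si' must be single lattice indices in 0..8")
  log(max(unclass(belief)[hi + 1, si + 1], PROB_FLOOR))
}
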