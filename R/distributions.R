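#' Sharpened (or blunted) binomial distribution
#'
#' Probability mass function of a binomial distribution over `0:size` raised
#' elementwise to the power `u` and renormalized. Exponents greater than 1
#' sharpen the distribution around its mode; exponents below 1 blunt it
#' towards uniformity; `u = 0` gives the discrete uniform. The mode of the
#' underlying binomial is preserved for every `u > 0`.
#'
#' This family is the workhorse of the intent-attribution model: it
#' parameterises the prior belief marginals over the 9-level harmful-intent
#' and self-interest lattices, and each row of the dictator policy map.
#'
#' @param p success probability, strictly inside (0, 1).
#' @param u sharpening exponent, a finite non-negative number.
#' @param size number of binomial trials; the support is `0:size`.
#' @return Numeric vector of length `size + 1` summing to 1.
#' @examples
#' sharpened_binomial(0.5, 1, 8)   # plain binomial pmf
#' sharpened_binomial(0.5, 0, 8)   # uniform over 9 outcomes
#' @export
sharpened_binomial <- function(p, u, size) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single probability strictly inside (0, 1)")
  if (length(u) != 1L || !is.finite(u) || u < 0)
    stop("'u' must be a single finite non-negative exponent")
  if (length(size) != 1L || !is.finite(size) || size < 1)
    stop("'size' must be a single positive trial count")
  lw <- u * stats::dbinom(0:size, size, p, log = TRUE)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Fixed constants of the dictator policy template
#'
#' The policy template maps each (harmful intent, self interest) attribute
#' pair to a distribution over the 9 possible return bins. Its shape is
#' governed by a priori fixed constants: the lattice size `n_pi`, the edge
#' probability `p_init` at the extremes of the return scale, the base
#' sharpening `u_init`, the implied per-level probability step
#' `delta_p = (1 - 2 p_init) / (n_pi - 1)`, and a small lapse rate
#' `xi = 0.02 / n_pi^2` added for numerical stability.
#'
#' @param n_pi lattice size (number of attribute levels and return bins).
#' @param p_init edge probability of the template.
#' @param u_init base sharpening exponent of the template.
#' @return An object of class `policy_constants`.
#' @examples
#' pc <- policy_constants()
#' pc$delta_p   # 0.1125
#' pc$xi        # 0.02 / 81
#' @export
policy_constants <- function(n_pi = 9L, p_init = 0.05, u_init = 2.5) {
  n_pi <- as.integer(n_pi)
  if (n_pi < 2L) stop("'n_pi' must be at least 2")
  if (!is.finite(p_init) || p_init <= 0 || p_init >= 0.5)
    stop("'p_init' must lie in (0, 0.5)")
  if (!is.finite(u_init) || u_init <= 0) stop("'u_init' must be positive")
  structure(
    list(
      n_pi = n_pi,
      p_init = p_init,
      u_init = u_init,
      delta_p = (1 - 2 * p_init) / (n_pi - 1),
      xi = 0.02 / n_pi^2
    ),
    class = "policy_constants"
  )
}

#' @export
print.policy_constants <- function(x, ...) {
  cat("Policy template constants\n")
  cat(sprintf("  n_pi = %d, p_init = %g, u_init = %g\n", x$n_pi, x$p_init, x$u_init))
  cat(sprintf("  delta_p = %g, lapse xi = %g\n", x$delta_p, x$xi))
  invisible(x)
}

#' Chance log-likelihood floor
#'
#' Log-probability of any single joint (harmful intent, self interest)
#' response under a model that hedges uniformly over all lattice cells:
#' `log(1 / n_pi^2)`, i.e. -4.394 for the default 9x9 lattice. Fitted
#' per-trial log-likelihoods should stay well above this floor.
#'
#' @param n_pi lattice size.
#' @return A single number, `log(1 / n_pi^2)`.
#' @export
chance_loglik <- function(n_pi = 9L) log(1 / as.numeric(n_pi)^2)

# Smallest cell probability admitted before taking logs.
PROB_FLOOR <- 1e-30
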