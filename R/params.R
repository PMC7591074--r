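#' Participant-level model parameters
#'
#' Bundles the six latent quantities characterising one participant:
#' the prior modes `pHI0`, `pSI0` (central tendency of the initial
#' harmful-intent and self-interest beliefs, on (0, 1)), the prior
#' uncertainties `uHI0`, `uSI0` (spread of those beliefs; larger means
#' flatter, i.e. reduced confidence), the partner policy uncertainty `u_pi`
#' (how loosely attributes are believed to map onto observed returns; larger
#' makes each observed return less informative), and the cross-partner
#' learning rate `eta` in [0, 1] (how much of the posterior about one
#' dictator seeds the prior for the next).
#'
#' @param pHI0,pSI0 prior modes, strictly inside (0, 1).
#' @param uHI0,uSI0 prior uncertainties, strictly positive.
#' @param u_pi policy uncertainty, strictly positive.
#' @param eta learning rate in [0, 1].
#' @return An object of class `participant_params` (a named list).
#' @examples
#' participant_params(pHI0 = 0.3, uHI0 = 1, pSI0 = 0.6, uSI0 = 1,
#'                    u_pi = 1, eta = 0.5)
#' @export
participant_params <- function(pHI0, uHI0, pSI0, uSI0, u_pi, eta) {
  vals <- c(pHI0 = pHI0, uHI0 = uHI0, pSI0 = pSI0, uSI0 = uSI0,
            u_pi = u_pi, eta = eta)
  if (length(vals) != 6L || !all(is.finite(vals)))
    stop("all six parameters must be single finite numbers")
  if (pHI0 <= 0 || pHI0 >= 1 || pSI0 <= 0 || pSI0 >= 1)
    stop("'pHI0' and 'pSI0' must lie strictly inside (0, 1)")
  if (uHI0 <= 0 || uSI0 <= 0)
    stop("'uHI0' and 'uSI0' must be strictly positive")
  if (u_pi <= 0) stop("'u_pi' must be strictly positive")
  if (eta < 0 || eta > 1) stop("'eta' must lie in [0, 1]")
  structure(as.list(vals), class = "participant_params")
}

#' @export
print.participant_params <- function(x, ...) {
  cat("Participant parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.numeric.participant_params <- function(x, ...) {
  unlist(x, use.names = TRUE)
}

PARAM_NAMES <- c("pHI0", "uHI0", "pSI0", "uSI0", "u_pi", "eta")

# Coerce a named vector / one-row data frame / participant_params to
# participant_params, validating on the way.
as_participant_params <- function(x) {
  if (inherits(x, "participant_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single row of parameters")
    x <- unlist(x[, PARAM_NAMES, drop = FALSE])
  }
  x <- x[PARAM_NAMES]
  if (anyNA(x)) stop("missing parameter values; need ",
                     paste(PARAM_NAMES, collapse = ", "))
  do.call(participant_params, as.list(x))
}
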