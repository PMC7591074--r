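# Session handling: one participant's 18 trials (3 dictator blocks x 6
# trials) in long format, and the definitional R implementation of the
# session log-likelihood. The compiled engine in src/ mirrors this exactly
# and is used by the fitting routines; the two are tested for agreement.

DICTATOR_TYPES <- c("fair", "partially_fair", "unfair")

TRIAL_COLUMNS <- c("participant_id", "gpts", "block_index", "dictator_type",
                   "trial", "return_bin", "hi_rating", "si_rating",
                   "order_label")

#' Validate and normalize one participant's session
#'
#' Checks that a long-format trial data frame holds exactly 3 dictator
#' blocks of 6 trials each, with recognized dictator types, return bins in
#' 1..9, ratings in 1..100, and (if present) a GPTS total in 32..160, then
#' orders rows by (block, trial).
#'
#' @param session a data frame with the trial-level columns
#'   `block_index`, `dictator_type`, `trial`, `return_bin`, `hi_rating`,
#'   `si_rating` (plus optionally `participant_id`, `gpts`, `order_label`).
#' @return The validated data frame, ordered by block and trial.
#' @export
validate_session <- function(session) {
  needed <- c("block_index", "dictator_type", "trial", "return_bin",
              "hi_rating", "si_rating")
  missing_cols <- setdiff(needed, names(session))
  if (length(missing_cols))
    stop("session is missing column(s): ", paste(missing_cols, collapse = ", "))
  id <- if ("participant_id" %in% names(session))
    as.character(session$participant_id[1]) else "<session>"
  if (nrow(session) != 18L)
    stop("participant ", id, " has ", nrow(session), " trials; expected 18")
  session <- session[order(session$block_index, session$trial), , drop = FALSE]
  if (!identical(as.integer(session$block_index), rep(1:3, each = 6L)))
    stop("participant ", id, " must have blocks 1..3 with 6 trials each")
  if (!identical(as.integer(session$trial), rep(1:6, times = 3L)))
    stop("participant ", id, " must have trials 1..6 within each block")
  bad_type <- setdiff(unique(as.character(session$dictator_type)), DICTATOR_TYPES)
  if (length(bad_type))
    stop("participant ", id, " has unknown dictator type(s): ",
         paste(bad_type, collapse = ", "))
  if (any(session$return_bin < 1 | session$return_bin > 9 |
          session$return_bin != as.integer(session$return_bin)))
    stop("participant ", id, ": column return_bin must hold integers in 1..9")
  for (col in c("hi_rating", "si_rating")) {
    v <- session[[col]]
    if (any(!is.finite(v) | v < 1 | v > 100))
      stop("participant ", id, ": column ", col,
           " must hold ratings between 1 and 100")
  }
  if ("gpts" %in% names(session)) {
    g <- session$gpts
    if (any(!is.na(g) & (g < 32 | g > 160)))
      stop("participant ", id, ": column gpts must lie between 32 and 160")
  }
  rownames(session) <- NULL
  session
}

#' Session log-likelihood under the belief model
#'
#' Runs the full belief recursion for one participant: the prior grid is
#' built from the participant's parameters; within each dictator block each
#' observed return triggers a Bayesian update; the reported (HI, SI) ratings
#' of each trial are scored as a joint draw from the belief grid (by default
#' the grid after incorporating that trial's return, since participants rate
#' after seeing the split; set `score = "pre"` to score the pre-update
#' belief); between blocks the next prior is the learning-rate mixture of
#' the block's starting prior and its final posterior.
#'
#' @param params a [participant_params()] object (or coercible).
#' @param session one participant's trials, see [validate_session()].
#' @param constants a [policy_constants()] object.
#' @param score whether ratings are scored against the post-update
#'   (`"post"`, default) or pre-update (`"pre"`) belief.
#' @param engine `"R"` for the reference implementation built from the
#'   exported operations, `"cpp"` for the compiled engine (identical
#'   results, used by the fitting routines).
#' @return A list with `total` (the summed log-likelihood over 18 trials)
#'   and `per_trial` (the length-18 vector of trial log-likelihoods).
#' @export
session_loglik <- function(params, session, constants = policy_constants(),
                           score = c("post", "pre"), engine = c("R", "cpp")) {
  params <- as_participant_params(params)
  score <- match.arg(score)
  engine <- match.arg(engine)
  session <- validate_session(session)
  hi <- rating_to_bin(session$hi_rating)
  si <- rating_to_bin(session$si_rating)
  r <- as.integer(session$return_bin)
  blk <- as.integer(session$block_index)

  if (engine == "cpp") {
    per_trial <- cpp_session_loglik(
      unlist(params), r, hi, si, blk,
      constants$n_pi, constants$p_init, constants$u_init,
      constants$delta_p, constants$xi, score == "post")
    return(list(total = sum(per_trial), per_trial = per_trial))
  }

  policy <- apply_policy_uncertainty(build_policy_template(constants),
                                     params$u_pi, constants)
  block_prior <- build_prior(params, constants)
  per_trial <- numeric(length(r))
  for (b in unique(blk)) {
    idx <- which(blk == b)
    belief <- block_prior
    for (t in idx) {
      pre <- belief
      belief <- bayes_update(belief, r[t], policy)
      scored <- if (score == "post") belief else pre
      per_trial[t] <- trial_loglik(scored, hi[t], si[t])
    }
    block_prior <- carry_over_prior(block_prior, belief, params$eta)
  }
  list(total = sum(per_trial), per_trial = per_trial)
}

# Split a long multi-participant trial data frame into a named list of
# per-participant sessions (order of first appearance).
split_sessions <- function(trials) {
  if (!"participant_id" %in% names(trials))
    stop("trial data must have a participant_id column")
  ids <- unique(as.character(trials$participant_id))
  sessions <- split(trials, factor(as.character(trials$participant_id),
                                   levels = ids))
  lapply(sessions, validate_session)
}
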