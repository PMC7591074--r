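# Forward simulation: dictator behaviour and participant attributions.

#' Simulate a dictator's return sequence
#'
#' Fair dictators always return half the endowment (bin 5); unfair
#' dictators always return nothing (bin 1); partially fair dictators
#' choose independently between the two with probability one half each
#' trial.
#'
#' @param type one of `"fair"`, `"partially_fair"`, `"unfair"`.
#' @param n_trials number of trials in the block.
#' @param seed optional RNG seed (only consulted for partially fair
#'   dictators).
#' @return Integer vector of return bins.
#' @export
simulate_dictator_returns <- function(type, n_trials = 6L, seed = NULL) {
  type <- as.character(type)
  if (length(type) != 1L || !type %in% DICTATOR_TYPES)
    stop("unknown dictator type: ", type)
  switch(type,
         fair = rep(5L, n_trials),
         unfair = rep(1L, n_trials),
         partially_fair = {
           if (!is.null(seed)) set.seed(seed)
           sample(c(1L, 5L), n_trials, replace = TRUE)
         })
}

#' Simulate one participant's session
#'
#' Runs the same belief recursion as [session_loglik()] at the given
#' parameters: within each dictator block, each observed return updates the
#' belief grid, and the reported attributions are a joint (HI, SI) cell
#' sampled from the scored belief (post-update by default), mapped back to
#' the 1-100 rating scale through bin centres. Between blocks the prior is
#' carried over with the learning rate.
#'
#' @param params a [participant_params()] object (or coercible).
#' @param order the dictator types in encounter order (a permutation of
#'   fair / partially_fair / unfair).
#' @param seed RNG seed; the run is fully reproducible given it.
#' @param id participant identifier written into the output.
#' @param gpts GPTS total carried into the output (or `NA`).
#' @param returns optional list of 3 return-bin vectors to replay instead
#'   of freshly simulated dictator behaviour.
#' @param constants a [policy_constants()] object.
#' @param score which belief the reported attributions are sampled from,
#'   matching the scoring convention of [session_loglik()].
#' @return One session as a long trial data frame (18 rows).
#' @export
simulate_participant <- function(params,
                                 order = c("fair", "partially_fair", "unfair"),
                                 seed = NULL, id = "sim1", gpts = NA,
                                 returns = NULL,
                                 constants = policy_constants(),
                                 score = c("post", "pre")) {
  params <- as_participant_params(params)
  score <- match.arg(score)
  order <- as.character(order)
  if (length(order) != 3L || !setequal(order, DICTATOR_TYPES))
    stop("'order' must be a permutation of the three dictator types")
  if (!is.null(seed)) set.seed(seed)
  n <- constants$n_pi
  policy <- apply_policy_uncertainty(build_policy_template(constants),
                                     params$u_pi, constants)
  block_prior <- build_prior(params, constants)
  rows <- vector("list", 3L)
  for (b in 1:3) {
    r <- if (!is.null(returns)) as.integer(returns[[b]])
         else simulate_dictator_returns(order[b], 6L)
    if (length(r) != 6L || any(r < 1L | r > n))
      stop("replayed returns for block ", b, " must be 6 bins in 1..", n)
    belief <- block_prior
    hi_rating <- si_rating <- integer(6L)
    for (t in 1:6) {
      pre <- belief
      belief <- bayes_update(belief, r[t], policy)
      scored <- if (score == "post") belief else pre
      cell <- sample.int(n * n, 1L, prob = as.vector(scored))
      # as.vector is column-major: HI index varies fastest
      hi_idx <- (cell - 1L) %% n
      si_idx <- (cell - 1L) %/% n
      hi_rating[t] <- bin_to_rating(hi_idx)
      si_rating[t] <- bin_to_rating(si_idx)
    }
    rows[[b]] <- data.frame(participant_id = id, gpts = gpts,
                            block_index = b, dictator_type = order[b],
                            trial = 1:6, return_bin = r,
                            hi_rating = hi_rating, si_rating = si_rating,
                            order_label = paste(order, collapse = "-"),
                            stringsAsFactors = FALSE)
    block_prior <- carry_over_prior(block_prior, belief, params$eta)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the three counterbalanced encounter orders (cyclic rotations)
dictator_orders <- function() {
  list(c("fair", "partially_fair", "unfair"),
       c("partially_fair", "unfair", "fair"),
       c("unfair", "fair", "partially_fair"))
}

#' Simulate a population of sessions
#'
#' Simulates one session per row of a parameter table, assigning the three
#' counterbalanced dictator orders cyclically and drawing an independent
#' per-participant RNG substream from the master seed.
#'
#' @param param_table data frame with one row per pseudo-participant:
#'   `participant_id` (optional), `gpts` (optional), and the six
#'   parameters.
#' @param seed master RNG seed.
#' @param constants a [policy_constants()] object.
#' @param score scoring convention passed to [simulate_participant()].
#' @return A long trial data frame of `18 * nrow(param_table)` rows.
#' @export
simulate_population <- function(param_table, seed = 1L,
                                constants = policy_constants(),
                                score = c("post", "pre")) {
  if (!is.data.frame(param_table) || nrow(param_table) == 0L)
    stop("'param_table' must be a non-empty data frame")
  score <- match.arg(score)
  n <- nrow(param_table)
  ids <- if ("participant_id" %in% names(param_table))
    as.character(param_table$participant_id) else sprintf("p%04d", seq_len(n))
  gpts <- if ("gpts" %in% names(param_table)) param_table$gpts else rep(NA, n)
  orders <- dictator_orders()
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  out <- lapply(seq_len(n), function(i)
    simulate_participant(param_table[i, , drop = FALSE],
                         order = orders[[(i - 1L) %% 3L + 1L]],
                         seed = seeds[i], id = ids[i], gpts = gpts[i],
                         constants = constants, score = score))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
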