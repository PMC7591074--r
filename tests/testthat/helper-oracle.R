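# Independent brute-force re-implementation of the belief model, written
# directly from the defining formulas with plain arithmetic (no shared code
# with the package internals). Used as the oracle in equivalence tests.

oracle_nb <- function(p, u, n) {
  w <- (choose(n, 0:n) * p^(0:n) * (1 - p)^(n - (0:n)))^u
  w / sum(w)
}

oracle_policy <- function(u_pi, n_pi = 9, p_init = 0.05, u_init = 2.5) {
  delta_p <- (1 - 2 * p_init) / (n_pi - 1)
  xi <- 0.02 / n_pi^2
  marg <- t(sapply(0:(n_pi - 1), function(a)
    oracle_nb(1 - p_init - delta_p * a, u_init - 2 * delta_p * (a + 1),
              n_pi - 1)))
  pol <- array(0, c(n_pi, n_pi, n_pi))
  for (i in 1:n_pi)
    for (j in 1:n_pi) {
      row <- marg[i, ] * marg[j, ]
      row <- row / sum(row)
      row <- row^(1 / u_pi) + xi
      pol[i, j, ] <- row / sum(row)
    }
  pol
}

oracle_prior <- function(par, n_pi = 9) {
  hi <- oracle_nb(par[["pHI0"]], 1 / par[["uHI0"]], n_pi - 1)
  si <- oracle_nb(par[["pSI0"]], 1 / par[["uSI0"]], n_pi - 1)
  joint <- outer(hi, si)
  joint / sum(joint)
}

# explicit cell-by-cell posterior
oracle_bayes <- function(belief, r, pol) {
  n <- dim(pol)[1]
  post <- matrix(0, n, n)
  for (i in 1:n)
    for (j in 1:n)
      post[i, j] <- belief[i, j] * pol[i, j, r]
  post / sum(post)
}

oracle_session <- function(par, session, score = "post") {
  session <- session[order(session$block_index, session$trial), ]
  pol <- oracle_policy(par[["u_pi"]])
  prior <- oracle_prior(par)
  hi <- pmin(8, floor(session$hi_rating * 9 / 100))
  si <- pmin(8, floor(session$si_rating * 9 / 100))
  r <- session$return_bin
  blk <- session$block_index
  ll <- numeric(nrow(session))
  block_prior <- prior
  for (b in unique(blk)) {
    idx <- which(blk == b)
    belief <- block_prior
    for (t in idx) {
      pre <- belief
      belief <- oracle_bayes(belief, r[t], pol)
      scored <- if (score == "post") belief else pre
      ll[t] <- log(max(scored[hi[t] + 1, si[t] + 1], 1e-30))
    }
    m <- (1 - par[["eta"]]) * block_prior + par[["eta"]] * belief
    block_prior <- m / sum(m)
  }
  ll
}

# random-but-valid fixtures -------------------------------------------------

random_params <- function() {
  c(pHI0 = runif(1, 0.1, 0.9), uHI0 = exp(runif(1, log(0.2), log(5))),
    pSI0 = runif(1, 0.1, 0.9), uSI0 = exp(runif(1, log(0.2), log(5))),
    u_pi = exp(runif(1, log(0.25), log(4))), eta = runif(1))
}

as_belief_params <- function(v) do.call(participant_params, as.list(v))

random_session <- function(id = "r1", gpts = 80) {
  data.frame(participant_id = id, gpts = gpts,
             block_index = rep(1:3, each = 6),
             dictator_type = rep(sample(c("fair", "partially_fair", "unfair")),
                                 each = 6),
             trial = rep(1:6, 3),
             return_bin = sample(1:9, 18, replace = TRUE),
             hi_rating = sample(1:100, 18, replace = TRUE),
             si_rating = sample(1:100, 18, replace = TRUE),
             order_label = "random", stringsAsFactors = FALSE)
}

grid_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
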