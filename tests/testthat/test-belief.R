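pc <- policy_constants()
policy1 <- apply_policy_uncertainty(build_policy_template(pc), 1, pc)

mean_hi <- function(b) sum(rowSums(unclass(b)) * (0:8))

test_that("the prior grid is the outer product of sharpened marginals", {
  p <- participant_params(0.5, 1, 0.5, 1, 1, 0.5)
  prior <- build_prior(p, pc)
  expect_equal(unclass(prior), outer(dbinom(0:8, 8, 0.5), dbinom(0:8, 8, 0.5)),
               tolerance = 1e-12)
  expect_lt(abs(sum(prior) - 1), 1e-9)
})

test_that("large prior uncertainty flattens the grid towards uniform", {
  p <- participant_params(0.3, 1e9, 0.7, 1e9, 1, 0.5)
  prior <- build_prior(p, pc)
  expect_equal(as.vector(unclass(prior)), rep(1 / 81, 81), tolerance = 1e-6)
  # lower uncertainty = sharper (lower entropy) HI marginal
  sharp <- build_prior(participant_params(0.9, 0.5, 0.5, 1, 1, 0.5), pc)
  flat <- build_prior(participant_params(0.9, 2, 0.5, 1, 1, 0.5), pc)
  expect_lt(grid_entropy(rowSums(sharp)), grid_entropy(rowSums(flat)))
})

test_that("zero prior uncertainty is rejected at construction", {
  expect_error(participant_params(0.5, 0, 0.5, 1, 1, 0.5), "uHI0")
})

test_that("a flat prior posterior is the normalized policy slice", {
  for (r in c(1L, 5L, 9L)) {
    post <- bayes_update(uniform_belief(pc), r, policy1)
    slice <- policy1[, , r]
    expect_equal(unclass(post), slice / sum(slice), tolerance = 1e-12)
  }
})

test_that("observing a take-all return raises the harmful-intent mean", {
  post <- bayes_update(uniform_belief(pc), 1, policy1)
  expect_gt(mean_hi(post), 4.0)
})

test_that("bayes_update matches the cell-by-cell oracle", {
  set.seed(41)
  for (i in 1:25) {
    par <- random_params()
    belief <- build_prior(as_belief_params(par), pc)
    r <- sample(1:9, 1)
    post <- bayes_update(belief, r, policy1)
    expect_equal(unclass(post), oracle_bayes(unclass(belief), r, policy1),
                 tolerance = 1e-12)
  }
})

test_that("posterior-prior KL shrinks as policy uncertainty flattens the map", {
  # on the flattening side (u_pi above ~1) each observed return carries
  # monotonically less information; below that the lapse caps how much a
  # hyper-sharpened policy can move the belief, so KL is not globally
  # monotone in u_pi
  prior <- build_prior(participant_params(0.3, 1, 0.6, 1, 1, 0.5), pc)
  kl <- vapply(c(1.5, 2, 3, 4, 6, 8, 12, 20), function(u) {
    pol <- apply_policy_uncertainty(build_policy_template(pc), u, pc)
    post <- bayes_update(prior, 1, pol)
    sum(unclass(post) * (log(unclass(post)) - log(unclass(prior))))
  }, 0)
  expect_true(all(diff(kl) < 1e-12))
  expect_lt(kl[length(kl)], 0.1)
})

test_that("extreme returns move the harmful-intent mean in the right direction", {
  # from an uninformative prior the direction is unambiguous
  m_take <- mean_hi(bayes_update(uniform_belief(pc), 1, policy1))
  m_give <- mean_hi(bayes_update(uniform_belief(pc), 9, policy1))
  expect_gt(m_take, 4)
  expect_lt(m_give, 4)
  # for arbitrary priors the per-cell normalization of the product template
  # makes the likelihood slightly non-monotone in HI at fixed SI, so the
  # direction holds in the large majority (not the entirety) of cases
  set.seed(42)
  ok_take <- ok_give <- 0L
  for (i in 1:50) {
    par <- random_params()
    prior <- build_prior(as_belief_params(par), pc)
    pol <- apply_policy_uncertainty(build_policy_template(pc), par[["u_pi"]], pc)
    m0 <- mean_hi(prior)
    ok_take <- ok_take + (mean_hi(bayes_update(prior, 1, pol)) >= m0 - 1e-9)
    ok_give <- ok_give + (mean_hi(bayes_update(prior, 9, pol)) <= m0 + 1e-9)
  }
  expect_gte(ok_take / 50, 0.8)
  expect_gte(ok_give / 50, 0.8)
})

test_that("carry-over is the exact convex mixture", {
  a <- build_prior(participant_params(0.2, 1, 0.8, 1, 1, 0.5), pc)
  b <- bayes_update(a, 1, policy1)
  expect_equal(unclass(carry_over_prior(a, b, 0)), unclass(a))
  expect_equal(unclass(carry_over_prior(a, b, 1)), unclass(b))
  half <- carry_over_prior(a, b, 0.5)
  expect_equal(unclass(half), (unclass(a) + unclass(b)) / 2, tolerance = 1e-12)
  expect_lt(abs(sum(half) - 1), 1e-9)
  expect_error(carry_over_prior(a, b, 1.2), "eta")
})

test_that("ratings map onto lattice bins and back through bin centres", {
  expect_identical(rating_to_bin(50), 4L)
  expect_identical(rating_to_bin(1), 0L)
  expect_identical(rating_to_bin(100), 8L)
  expect_error(rating_to_bin(0), "between")
  expect_error(rating_to_bin(101), "between")
  expect_identical(bin_to_rating(4L), 50L)
  # round trip: a bin's centre rating falls back into the same bin
  expect_identical(rating_to_bin(bin_to_rating(0:8)), 0:8)
})

test_that("trial log-likelihood scores the joint reported cell", {
  expect_equal(trial_loglik(uniform_belief(pc), 4, 4), log(1 / 81))
  expect_equal(round(trial_loglik(uniform_belief(pc), 0, 8), 3), -4.394)
  point <- matrix(0, 9, 9); point[3, 7] <- 1
  expect_equal(trial_loglik(intentgame:::new_belief_grid(point), 2, 6), 0)
  quarter <- matrix((1 - 0.25) / 80, 9, 9); quarter[5, 5] <- 0.25
  expect_equal(trial_loglik(intentgame:::new_belief_grid(quarter), 4, 4),
               log(0.25))
})
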