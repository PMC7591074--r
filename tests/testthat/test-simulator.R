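base_params <- participant_params(0.3, 1, 0.6, 1, 1, 0.5)

test_that("dictator behaviour follows its type", {
  expect_identical(simulate_dictator_returns("fair", 6), rep(5L, 6))
  expect_identical(simulate_dictator_returns("unfair", 6), rep(1L, 6))
  expect_error(simulate_dictator_returns("generous", 6), "generous")
  a <- simulate_dictator_returns("partially_fair", 6, seed = 4)
  b <- simulate_dictator_returns("partially_fair", 6, seed = 4)
  expect_identical(a, b)
  expect_true(all(a %in% c(1L, 5L)))
  long <- simulate_dictator_returns("partially_fair", 10000, seed = 8)
  expect_lt(abs(mean(long == 5L) - 0.5), 0.015)
})

test_that("a degenerate antisocial prior pins every rating to the top bin", {
  p <- participant_params(0.999, 0.05, 0.999, 0.05, 1e8, 0)
  for (ord in list(c("fair", "partially_fair", "unfair"),
                   c("unfair", "fair", "partially_fair"))) {
    sess <- simulate_participant(p, order = ord, seed = 51, gpts = 80)
    expect_true(all(sess$hi_rating == bin_to_rating(8L)))
    expect_true(all(sess$si_rating == bin_to_rating(8L)))
  }
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_participant(base_params, seed = 52, gpts = 80)
  b <- simulate_participant(base_params, seed = 52, gpts = 80)
  expect_identical(a, b)
  c <- simulate_participant(base_params, seed = 53, gpts = 80)
  expect_false(identical(a, c))
})

test_that("generating parameters beat a distant point on their own data", {
  far <- participant_params(0.9, 5, 0.1, 5, 10, 1)
  wins <- 0L
  for (i in 1:30) {
    sess <- simulate_participant(base_params, seed = 600 + i, gpts = 80)
    wins <- wins + (session_loglik(base_params, sess)$total >
                      session_loglik(far, sess)$total)
  }
  expect_gte(wins / 30, 0.9)
})

test_that("unfair dictators elicit higher harmful intent than fair ones", {
  set.seed(61)
  hi_gap <- replicate(10, {
    par <- random_params()
    par["u_pi"] <- min(par[["u_pi"]], 2)
    sess <- simulate_participant(as_belief_params(par),
                                 seed = sample.int(1e6, 1), gpts = 80)
    mean(sess$hi_rating[sess$dictator_type == "unfair"]) -
      mean(sess$hi_rating[sess$dictator_type == "fair"])
  })
  expect_gt(mean(hi_gap), 0)
  expect_gte(mean(hi_gap > 0), 0.8)
})

test_that("population simulation counterbalances orders and keeps the schema", {
  pt <- generate_population(population_spec(n = 9, seed = 71))
  trials <- simulate_population(pt, seed = 72)
  expect_identical(nrow(trials), 18L * 9L)
  orders <- unique(trials[, c("participant_id", "order_label")])$order_label
  expect_identical(as.vector(table(orders)), rep(3L, 3))
  # round trip through disk keeps everything scoreable
  tmp <- tempfile(fileext = ".csv")
  write_trials(trials, tmp)
  back <- read_trials(tmp)
  sessions <- intentgame:::split_sessions(back)
  ll <- session_loglik(base_params, sessions[[1]])
  expect_true(is.finite(ll$total))
  expect_identical(nrow(back), nrow(trials))
})

test_that("a paranoia-coupled population shows the GPTS/harmful-intent link", {
  pt <- generate_population(population_spec(n = 150, seed = 73))
  trials <- simulate_population(pt, seed = 74)
  per <- aggregate(hi_rating ~ participant_id + gpts, trials, mean)
  expect_gt(cor(per$gpts, per$hi_rating, method = "spearman"), 0)
})
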