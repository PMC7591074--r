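cfg <- fit_config()
base_params <- participant_params(0.3, 1, 0.6, 1, 1, 0.5)

test_that("the regularizing prior is finite inside and -Inf outside bounds", {
  expect_true(is.finite(log_prior(base_params, cfg)))
  p <- unlist(base_params)
  p["eta"] <- 1.2
  expect_identical(log_prior(p, cfg), -Inf)
  p <- unlist(base_params)
  p["u_pi"] <- 30
  expect_identical(log_prior(p, cfg), -Inf)
})

test_that("the uncertainty-scale penalty follows the log-normal density", {
  a <- unlist(base_params); a["u_pi"] <- 1
  b <- unlist(base_params); b["u_pi"] <- exp(1.5)
  expect_equal(log_prior(a, cfg) - log_prior(b, cfg),
               dlnorm(1, 0, 1.5, log = TRUE) - dlnorm(exp(1.5), 0, 1.5,
                                                      log = TRUE),
               tolerance = 1e-12)
})

test_that("grid search finds a high prior mode planted in the data", {
  # a participant always reporting extreme harmful intent
  p <- participant_params(0.9, 0.1, 0.5, 0.3, 0.5, 0.2)
  sess <- simulate_participant(p, seed = 21, gpts = 80)
  seeds <- grid_search(sess, cfg)
  expect_equal(seeds$pHI0[1], max(cfg$grids$pHI0))
})

test_that("asking for more seeds than grid points returns the full sorted grid", {
  small <- fit_config(pHI0_grid = c(0.3, 0.7), uHI0_grid = c(0.5, 2),
                      uSI0_grid = c(0.5, 2), u_pi_grid = c(0.5, 2),
                      eta_grid = c(0.2, 0.8))
  sess <- simulate_participant(base_params, seed = 22, gpts = 80)
  out <- grid_search(sess, small, k = 10000)
  expect_identical(nrow(out), 64L)
  expect_true(all(diff(out$lp) <= 1e-12))
})

test_that("grid search is deterministic, including its tie-breaking", {
  sess <- simulate_participant(base_params, seed = 23, gpts = 80)
  a <- grid_search(sess, cfg)
  b <- grid_search(sess, cfg)
  expect_identical(a, b)
})

test_that("MAP ascent never falls below its grid seeds and respects the floor", {
  sess <- simulate_participant(base_params, seed = 24, gpts = 80)
  fit <- fit_intent(sess, cfg)
  expect_gte(fit$lp, max(fit$seeds$lp) - 1e-9)
  expect_true(all(fit$per_trial >= log(1e-30)))
  expect_equal(sum(fit$per_trial), fit$loglik, tolerance = 1e-8)
  expect_equal(fit$lp, fit$loglik + log_prior(fit$params, cfg),
               tolerance = 1e-8)
})

test_that("refitting the same data reproduces the result bit for bit", {
  sess <- simulate_participant(base_params, seed = 25, gpts = 80)
  a <- fit_intent(sess, cfg)
  b <- fit_intent(sess, cfg)
  expect_identical(unlist(a$params), unlist(b$params))
  expect_identical(a$lp, b$lp)
  expect_identical(a$per_trial, b$per_trial)
})

test_that("extreme learning rates are recovered on the correct half of [0, 1]", {
  base <- list(pHI0 = 0.2, uHI0 = 0.5, pSI0 = 0.5, uSI0 = 0.5, u_pi = 0.5)
  ok <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    eta_true <- if (i %% 2 == 0) 0 else 1
    p <- do.call(participant_params, c(base, list(eta = eta_true)))
    sess <- simulate_participant(p, order = c("fair", "unfair",
                                              "partially_fair"),
                                 seed = 1000 + i, gpts = 80)
    f <- fit_intent(sess, cfg)
    ok <- ok + ((coef(f)[["eta"]] > 0.5) == (eta_true > 0.5))
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("fit methods expose the model the standard way", {
  sess <- simulate_participant(base_params, seed = 26, gpts = 80)
  fit <- fit_intent(sess, cfg)
  expect_named(coef(fit), c("pHI0", "uHI0", "pSI0", "uSI0", "u_pi", "eta"))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_identical(attr(ll, "df"), 6L)
  pred <- predict(fit)
  expect_identical(nrow(pred), 18L)
  expect_true(all(pred$hi_expected >= 1 & pred$hi_expected <= 100))
  res <- residuals(fit)
  expect_equal(res[, "hi"], sess$hi_rating - pred$hi_expected,
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_identical(nrow(sims), 36L)
  # replayed returns match the fitted session
  expect_identical(sims$return_bin[1:18], sess$return_bin)
  expect_output(print(fit), "log-posterior")
  expect_output(print(summary(fit)), "chance floor")
})

test_that("fit_population collects per-participant rows and failures", {
  pt <- generate_population(population_spec(n = 4, seed = 31))
  trials <- simulate_population(pt, seed = 32)
  fitted <- fit_population(trials, cfg)
  expect_identical(nrow(fitted), 4L)
  expect_true(all(c("participant_id", "gpts", "lp", "loglik",
                    "converged") %in% names(fitted)))
  expect_identical(attr(fitted, "n_failed"), 0L)
  expect_true(all(fitted$gpts == pt$gpts[match(fitted$participant_id,
                                               pt$participant_id)]))
})
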