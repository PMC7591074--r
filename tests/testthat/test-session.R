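base_params <- participant_params(0.3, 1, 0.6, 1, 1, 0.5)

test_that("uniform-belief parameters score every trial at the chance floor", {
  sess <- simulate_participant(base_params, seed = 5, gpts = 80)
  flat <- participant_params(0.5, 1e8, 0.5, 1e8, 1e8, 0.5)
  ll <- session_loglik(flat, sess)
  expect_equal(ll$per_trial, rep(log(1 / 81), 18), tolerance = 1e-4)
  expect_equal(ll$total, 18 * log(1 / 81), tolerance = 1e-3)
})

test_that("the learning rate cannot affect the first dictator block", {
  sess <- simulate_participant(base_params, seed = 7, gpts = 80)
  p0 <- participant_params(0.3, 1, 0.6, 1, 1, 0)
  p1 <- participant_params(0.3, 1, 0.6, 1, 1, 1)
  a <- session_loglik(p0, sess)$per_trial
  b <- session_loglik(p1, sess)$per_trial
  expect_equal(a[1:6], b[1:6], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a[7:18], b[7:18], tolerance = 1e-6)))
})

test_that("session log-likelihood matches the step-by-step oracle", {
  set.seed(11)
  for (i in 1:10) {
    par <- random_params()
    sess <- random_session()
    ll <- session_loglik(as_belief_params(par), sess)
    expect_equal(ll$per_trial, oracle_session(par, sess), tolerance = 1e-12)
    expect_equal(ll$total, sum(oracle_session(par, sess)), tolerance = 1e-10)
  }
})

test_that("the compiled engine reproduces the reference implementation", {
  set.seed(12)
  for (i in 1:10) {
    par <- as_belief_params(random_params())
    sess <- random_session()
    for (score in c("post", "pre")) {
      a <- session_loglik(par, sess, score = score, engine = "R")
      b <- session_loglik(par, sess, score = score, engine = "cpp")
      expect_equal(a$per_trial, b$per_trial, tolerance = 1e-12)
    }
  }
})

test_that("pre-update scoring scores the first trial against the prior", {
  set.seed(13)
  sess <- random_session()
  par <- as_belief_params(random_params())
  pre <- session_loglik(par, sess, score = "pre")
  prior <- build_prior(par)
  expect_equal(pre$per_trial[1],
               trial_loglik(prior, rating_to_bin(sess$hi_rating[1]),
                            rating_to_bin(sess$si_rating[1])),
               tolerance = 1e-12)
  post <- session_loglik(par, sess, score = "post")
  expect_false(isTRUE(all.equal(pre$total, post$total, tolerance = 1e-6)))
})

test_that("session validation names the offending participant and column", {
  sess <- simulate_participant(base_params, seed = 9, id = "px17", gpts = 80)
  expect_error(validate_session(sess[-3, ]), "px17.*17", perl = TRUE)
  bad <- sess; bad$hi_rating[2] <- 0
  expect_error(validate_session(bad), "hi_rating")
  bad <- sess; bad$dictator_type <- "generous"
  expect_error(validate_session(bad), "generous")
  bad <- sess; bad$gpts <- 20
  expect_error(validate_session(bad), "gpts")
})
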