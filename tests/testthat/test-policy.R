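pc <- policy_constants()
template <- build_policy_template(pc)

test_that("policy template rows are distributions with the printed corner modes", {
  for (i in 1:9)
    for (j in 1:9) {
      expect_true(all(template[i, j, ] >= 0))
      expect_lt(abs(sum(template[i, j, ]) - 1), 1e-9)
    }
  # fully altruistic dictator prefers returning everything, fully
  # antisocial one prefers returning nothing
  expect_identical(which.max(template[1, 1, ]), 9L)
  expect_identical(which.max(template[9, 9, ]), 1L)
})

test_that("template marginals match the brute-force construction", {
  oracle <- oracle_policy(1)
  pol1 <- apply_policy_uncertainty(template, 1, pc)
  expect_equal(as.vector(unclass(pol1)), as.vector(oracle), tolerance = 1e-12)
})

test_that("template exponents stay positive under the default constants", {
  # smallest exponent occurs at the top attribute level
  expect_equal(pc$u_init - 2 * pc$delta_p * 9, 0.475)
  bad <- policy_constants(u_init = 0.3)
  expect_error(build_policy_template(bad), "exponent")
})

test_that("policy uncertainty flattens rows monotonically towards uniform", {
  maxima <- vapply(c(0.5, 1, 2, 5), function(u) {
    pol <- apply_policy_uncertainty(template, u, pc)
    max(pol[9, 9, ])
  }, 0)
  expect_true(all(diff(maxima) < 0))
  h1 <- grid_entropy(apply_policy_uncertainty(template, 1, pc)[9, 9, ])
  h2 <- grid_entropy(apply_policy_uncertainty(template, 2, pc)[9, 9, ])
  expect_gt(h2, h1)
  pol_inf <- apply_policy_uncertainty(template, 1e9, pc)
  expect_equal(pol_inf[4, 7, ], rep(1 / 9, 9), tolerance = 1e-6)
})

test_that("unit policy uncertainty preserves the template up to the lapse", {
  pol <- apply_policy_uncertainty(template, 1, pc)
  row <- template[3, 5, ] + pc$xi
  expect_equal(pol[3, 5, ], row / sum(row), tolerance = 1e-12)
  expect_true(all(pol >= pc$xi / (1 + 9 * pc$xi) - 1e-15))
})

test_that("policy stage flags are enforced", {
  expect_error(apply_policy_uncertainty(template, 0), "u_pi")
  pol <- apply_policy_uncertainty(template, 1, pc)
  expect_error(apply_policy_uncertainty(pol, 1, pc), "raw")
  expect_error(bayes_update(uniform_belief(pc), 1, template), "uncertainty")
})
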