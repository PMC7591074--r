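test_that("partial correlations recover a planted three-variable structure", {
  set.seed(9)
  x <- rnorm(300)
  y <- 0.7 * x + rnorm(300, sd = 0.5)
  z <- rnorm(300)
  pc <- intentgame:::pcor_matrix(cbind(x = x, y = y, z = z))
  expect_gt(pc["x", "y"], 0.5)
  expect_lt(abs(pc["x", "z"]), 0.15)
  expect_lt(abs(pc["y", "z"]), 0.15)
  expect_equal(diag(pc), c(x = 0, y = 0, z = 0))
})

test_that("independent parameters produce a near-empty network", {
  set.seed(7)
  n <- 500
  pt <- data.frame(pHI0 = runif(n, 0.05, 0.95), uHI0 = exp(runif(n, -1, 1)),
                   pSI0 = runif(n, 0.05, 0.95), uSI0 = exp(runif(n, -1, 1)),
                   u_pi = exp(runif(n, -1, 1)), eta = runif(n))
  net <- parameter_network(pt, B = 200, seed = 3)
  expect_identical(nrow(net$edges), 15L)
  expect_lt(max(abs(net$edges$pcor)), 0.15)
  expect_gte(sum(net$edges$lo <= 0 & net$edges$hi >= 0), 13L)
})

test_that("a planted moderated slope is recovered in sign", {
  set.seed(8)
  n <- 400
  z <- rnorm(n)
  x <- rnorm(n)
  eta <- (0.5 - 0.4 * z) * x + rnorm(n, sd = 0.5)
  pt <- data.frame(pHI0 = x, uHI0 = rnorm(n), pSI0 = rnorm(n),
                   uSI0 = rnorm(n), u_pi = rnorm(n), eta = eta)
  net <- parameter_network(pt, moderator = z, B = 50, seed = 4)
  inter <- net$moderation
  expect_lt(inter$interaction[inter$var1 == "pHI0" & inter$var2 == "eta"], 0)
})

test_that("the network stage enforces its minimum sample size", {
  pt <- generate_population(population_spec(n = 5, seed = 41))
  expect_error(parameter_network(pt, B = 10), "8")
})

test_that("a singular input falls back to the ridge regularizer", {
  n <- 60
  set.seed(10)
  x <- rnorm(n)
  pt <- data.frame(pHI0 = x, uHI0 = x, pSI0 = x, uSI0 = x, u_pi = x, eta = x)
  expect_message(net <- parameter_network(pt, B = 5, seed = 5), "ridge")
  expect_true(all(is.finite(net$edges$pcor)))
})
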