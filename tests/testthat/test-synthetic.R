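test_that("zero coupling and zero noise collapse to the intercepts", {
  spec <- population_spec(n = 5, couplings = setNames(rep(0, 6),
                                                      names(population_spec()$couplings)),
                          noise = setNames(rep(0, 6),
                                           names(population_spec()$noise)),
                          seed = 81)
  pt <- generate_population(spec)
  expect_equal(pt$pHI0, rep(plogis(spec$intercepts[["pHI0"]]), 5))
  expect_equal(pt$u_pi, rep(1, 5))
  expect_identical(length(unique(pt$eta)), 1L)
})

test_that("GPTS totals respect the instrument's range", {
  pt <- generate_population(population_spec(n = 10000, seed = 82))
  expect_gte(min(pt$gpts), 32)
  expect_lte(max(pt$gpts), 160)
  # right-skewed: mean above median
  expect_gt(mean(pt$gpts), median(pt$gpts))
})

test_that("every generated row satisfies the parameter invariants", {
  pt <- generate_population(population_spec(n = 500, seed = 83))
  for (i in seq_len(nrow(pt)))
    expect_s3_class(intentgame:::as_participant_params(pt[i, ]),
                    "participant_params")
})

test_that("the default couplings induce a positive GPTS/policy-uncertainty link", {
  pt <- generate_population(population_spec(n = 1000, seed = 84))
  expect_gt(cor(pt$gpts, pt$u_pi, method = "spearman"), 0)
  expect_gt(cor(pt$gpts, pt$pHI0, method = "spearman"), 0)
})

test_that("generation is reproducible under the spec seed", {
  a <- generate_population(population_spec(n = 50, seed = 85))
  b <- generate_population(population_spec(n = 50, seed = 85))
  expect_identical(a, b)
})

test_that("cluster populations stay within the printed ranges", {
  low <- generate_cluster_population("low", 200, seed = 86)
  expect_true(all(low$pHI0 >= 0.01 & low$pHI0 <= 0.2))
  expect_true(all(low$pSI0 >= 0.01 & low$pSI0 <= 0.2))
  med <- generate_cluster_population("medium", 200, seed = 87)
  expect_true(all(med$pHI0 >= 0.25 & med$pHI0 <= 0.5))
  expect_true(all(med$pSI0 >= 0.5 & med$pSI0 <= 0.75))
  high <- generate_cluster_population("high", 200, seed = 88)
  expect_true(all(high$pHI0 >= 0.01 & high$pHI0 <= 0.98))
  expect_true(all(high$pSI0 >= 0.8 & high$pSI0 <= 0.98))
  expect_error(generate_cluster_population("extreme", 10), "arg")
  expect_identical(generate_cluster_population("low", 20, seed = 89),
                   generate_cluster_population("low", 20, seed = 89))
})
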