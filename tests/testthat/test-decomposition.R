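test_that("direct + indirect equals the total exactly, and shares are ratios of components", {
  res <- decomposition_result(6883, 4642)
  expect_equal(res$indirect, 2241)
  expect_equal(res$direct + res$indirect, res$total)
  expect_equal(round(res$indirect_share, 1), 32.6)
  # undefined share when the total is not positive: flagged, not an error
  res0 <- decomposition_result(-10, 5)
  expect_false(res0$share_defined)
  expect_true(is.na(res0$indirect_share))
})

test_that("explanatory sets must be disjoint from the base covariates", {
  expect_error(decomposition_spec("cfi", base_covariates = c("age", "cfi")),
               "overlap")
  expect_error(decomposition_spec("cfi", n_reps = 1), "at least 2")
})

test_that("decompose_costs satisfies additivity on fitted data", {
  d <- analysis_cohort(n = 1200, seed = 5)
  for (set in c("functional_impairments", "phenotypic_frailty", "cfi", "all_three")) {
    res <- decompose_costs(d, decomposition_spec(set, n_reps = 10, seed = 1))
    expect_identical(res$indirect, res$total - res$direct)
    expect_equal(res$direct + res$indirect, res$total)
    expect_equal(res$indirect_share, 100 * res$indirect / res$total)
  }
})

test_that("the same seed gives bit-identical bootstrap results", {
  d <- analysis_cohort(n = 500, seed = 8)
  spec <- decomposition_spec("cfi", n_reps = 40, seed = 99)
  b1 <- bootstrap_decomposition(d, spec)
  b2 <- bootstrap_decomposition(d, spec)
  expect_identical(b1$ci_total, b2$ci_total)
  expect_identical(b1$ci_indirect, b2$ci_indirect)
  expect_identical(b1$replicates, b2$replicates)
  # a different seed moves the intervals
  b3 <- bootstrap_decomposition(d, decomposition_spec("cfi", n_reps = 40, seed = 100))
  expect_false(identical(b1$ci_total, b3$ci_total))
})

test_that("degenerate two-point data yield zero-width intervals", {
  # every exposed row identical and every unexposed row identical: any
  # resample reproduces the same two group means, so there is no sampling
  # variability for the bootstrap to see
  d <- data.frame(
    annualized_thc = rep(c(1000, 3000), each = 30),
    cognitively_impaired = rep(c(0L, 1L), each = 30),
    adl_category = factor(0, levels = 0:4),
    sex = "female"
  )
  spec <- decomposition_spec("functional_impairments",
                             base_covariates = character(0),
                             n_reps = 30, seed = 4)
  b <- bootstrap_decomposition(d, spec)
  expect_equal(diff(b$ci_total), 0, tolerance = 1e-6)
  expect_equal(b$total, 2000, tolerance = 1e-6)
})

test_that("null mediation leaves the indirect component near zero", {
  d <- analysis_cohort("null", n = 4000, seed = 13)
  spec <- decomposition_spec("all_three", n_reps = 120, seed = 7)
  b <- bootstrap_decomposition(d, spec)
  se <- sd(b$replicates[, "indirect"])
  expect_lt(abs(b$indirect), 3 * se)
})

test_that("pure mediation leaves the direct component near zero", {
  d <- analysis_cohort("pure-mediation", n = 4000, seed = 29)
  spec <- decomposition_spec("all_three", n_reps = 120, seed = 17)
  b <- bootstrap_decomposition(d, spec)
  se <- sd(b$replicates[, "direct"])
  expect_lt(abs(b$direct), 3 * se)
})

test_that("pooling weights components as stated and degenerates correctly", {
  res_f <- decomposition_result(6883, 4642); res_f$n_obs <- 4318
  res_m <- decomposition_result(7276, 4356); res_m$n_obs <- 3847
  eq <- pool_sexes(res_f, res_m, "equal")
  expect_equal(eq$total, 7079.5)
  expect_equal(eq$direct, (4642 + 4356) / 2)
  expect_equal(eq$direct + eq$indirect, eq$total)
  # by_n with equal stratum sizes collapses to equal weights
  res_f2 <- res_f; res_f2$n_obs <- 1000
  res_m2 <- res_m; res_m2$n_obs <- 1000
  expect_equal(pool_sexes(res_f2, res_m2, "by_n")$total, eq$total)
  # weights (1, 0) return the female result unchanged
  only_f <- pool_sexes(res_f, res_m, c(1, 0))
  expect_equal(only_f$total, res_f$total)
  expect_equal(only_f$direct, res_f$direct)
  # mismatched explanatory sets refuse to pool
  res_x <- decomposition_result(1, 1, explanatory = "cfi")
  expect_error(pool_sexes(res_f, res_x), "different explanatory")
})

test_that("pooled intervals come from weighted replicates when available", {
  d_f <- analysis_cohort(n = 400, seed = 31)
  d_m <- analysis_cohort(sex = "male", n = 400, seed = 32)
  spec <- decomposition_spec("cfi", n_reps = 40, seed = 3)
  b_f <- bootstrap_decomposition(d_f, spec)
  b_m <- bootstrap_decomposition(d_m, spec)
  pooled <- pool_sexes(b_f, b_m, "equal")
  expect_identical(pooled$ci_method, "pooled_replicates")
  expect_equal(
    pooled$ci_indirect,
    unname(quantile(0.5 * b_f$replicates[, "indirect"] +
                      0.5 * b_m$replicates[, "indirect"], c(0.025, 0.975)))
  )
})

test_that("strengthening mediator cost effects never shrinks the expected indirect share", {
  shares <- vapply(c(0.5, 1, 1.5), function(k) {
    pars <- generative_params("medicare-like", "female", 20000, seed = 101,
                              overrides = list(
                                beta_adl = k * c(0, 0.15, 0.30, 0.45, 0.60),
                                beta_frailty = k * c(robust = 0, prefrail = 0.12,
                                                     frail = 0.30),
                                beta_cfi = k * 1.8
                              ))
    d <- add_annualized_costs(phenotype_cohort(generate_cohort(pars)))
    res <- decompose_costs(d, decomposition_spec("all_three", n_reps = 10, seed = 1))
    res$indirect_share
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})
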