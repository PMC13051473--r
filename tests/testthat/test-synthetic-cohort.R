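test_that("a fixed seed regenerates a bit-identical cohort", {
  p <- generative_params("medicare-like", "male", 400, seed = 55)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  c3 <- generate_cohort(generative_params("medicare-like", "male", 400, seed = 56))
  expect_false(identical(c1$cumulative_cost, c3$cumulative_cost))
})

test_that("raw measures round-trip exactly through phenotyping", {
  for (sex in c("female", "male")) {
    coh <- generate_cohort(generative_params("medicare-like", sex, 1200,
                                             seed = if (sex == "female") 3 else 4))
    ph <- phenotype_cohort(coh)
    tr <- attr(coh, "truth")
    expect_identical(ph$cognitively_impaired, tr$ci)
    expect_identical(ph$n_adl_impairments, tr$n_adl_impairments)
    expect_identical(ph$frailty_component_count, tr$frailty_component_count)
    expect_identical(ph$comorbidity_count, tr$comorbidity_count)
    expect_true(all(ph$phenotype_complete))
  }
})

test_that("generated cohorts survive a CSV round trip", {
  coh <- generate_cohort(generative_params("medicare-like", "female", 150, seed = 21))
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  expect_true(file.exists(paste0(path, ".provenance.json")))
  prov <- jsonlite::read_json(paste0(path, ".provenance.json"))
  expect_equal(prov$n, 150)
  back <- read.csv(path, stringsAsFactors = FALSE)
  ph <- phenotype_cohort(back, norms = attr(coh, "reference_norms"))
  expect_identical(ph$cognitively_impaired, attr(coh, "truth")$ci)
  expect_identical(ph$comorbidity_count, attr(coh, "truth")$comorbidity_count)
  unlink(c(path, paste0(path, ".provenance.json")))
})

test_that("invalid generative parameters are rejected before any draw", {
  expect_error(generative_params(overrides = list(gamma_shape = -1)), "gamma_shape")
  expect_error(generative_params(overrides = list(ci_prevalence = 1.2)),
               "probabilities")
  expect_error(generative_params(overrides = list(adl_cutpoints = c(-1, 0, -2, -3))),
               "non-increasing")
  expect_error(generative_params(overrides = list(nonsense = 1)), "unknown")
})

test_that("cost distribution is right-skewed for low gamma shapes", {
  d <- analysis_cohort(n = 3000, seed = 77)
  y <- d$annualized_thc
  skew <- mean((y - mean(y))^3) / sd(y)^3
  expect_gt(skew, 0)
})

test_that("the medicare-like preset reproduces the qualitative group contrasts", {
  for (sex in c("female", "male")) {
    d <- analysis_cohort(sex = sex, n = 4000, seed = if (sex == "female") 61 else 62)
    ci <- d$cognitively_impaired == 1L
    expect_gt(mean(d$age[ci]), mean(d$age[!ci]))
    expect_gt(mean(d$frailty_category[ci] == "frail"),
              mean(d$frailty_category[!ci] == "frail"))
    expect_gt(mean(d$n_adl_impairments[ci]), mean(d$n_adl_impairments[!ci]))
    expect_gt(mean(d$comorbidity_count[ci]), mean(d$comorbidity_count[!ci]))
    expect_gt(mean(d$cfi[ci]), mean(d$cfi[!ci]))
    expect_gt(mean(d$annualized_thc[ci]), mean(d$annualized_thc[!ci]))
    expect_gt(mean(d$died[ci]), mean(d$died[!ci]))
  }
})

test_that("medicare-like prevalence lands within 1.5 points of the 12.1% target at n = 4318", {
  d <- phenotype_cohort(generate_cohort(generative_params("medicare-like", "female",
                                                          seed = 123)))
  prev <- 100 * mean(d$cognitively_impaired)
  expect_lt(abs(prev - 12.1), 1.5)
})

test_that("the null preset produces no group cost difference beyond noise", {
  d <- analysis_cohort("null", n = 5000, seed = 19)
  ci <- d$cognitively_impaired == 1L
  diff_mean <- mean(d$annualized_thc[ci]) - mean(d$annualized_thc[!ci])
  se <- sqrt(var(d$annualized_thc[ci]) / sum(ci) +
               var(d$annualized_thc[!ci]) / sum(!ci))
  expect_lt(abs(diff_mean), 3 * se)
})

test_that("the g-computation oracle degenerates correctly at the null and pure-mediation corners", {
  p_null <- generative_params("null", "female", 100, seed = 1)
  o_null <- decomposition_oracle(p_null, "all_three", n_mc = 50000, seed = 2)
  expect_lt(abs(o_null$true_indirect), 3 * max(o_null$mc_se_indirect, 1e-12))
  expect_equal(o_null$true_direct + o_null$true_indirect, o_null$true_total)

  p_med <- generative_params("pure-mediation", "female", 100, seed = 1)
  o_med <- decomposition_oracle(p_med, "all_three", n_mc = 50000, seed = 2)
  expect_lt(abs(o_med$true_direct), 3 * max(o_med$mc_se_direct, 1e-12))
  expect_gt(o_med$true_indirect, 0)
})

test_that("doubling the CFI cost coefficient raises the true indirect effect", {
  p1 <- generative_params("medicare-like", "female", 100, seed = 1)
  p2 <- generative_params("medicare-like", "female", 100, seed = 1,
                          overrides = list(beta_cfi = 3.6))
  o1 <- decomposition_oracle(p1, "cfi", n_mc = 60000, seed = 5)
  o2 <- decomposition_oracle(p2, "cfi", n_mc = 60000, seed = 5)
  expect_gt(o2$true_indirect, o1$true_indirect)
})
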