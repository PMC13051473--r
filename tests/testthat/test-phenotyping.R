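test_that("cohort cognitive-impairment rule honours diagnosis and the inclusive 1.5-SD cutoff", {
  norms <- toy_norms()  # mean 90, SD 6 in every stratum -> cutoff 81.0
  # diagnosis alone suffices, whatever the score
  expect_true(classify_cognitive_impairment_cohort(95, TRUE, "9to12", norms))
  # boundary is inclusive: exactly mean - 1.5 SD counts as impaired
  expect_true(classify_cognitive_impairment_cohort(81.0, FALSE, "9to12", norms))
  expect_false(classify_cognitive_impairment_cohort(81.1, FALSE, "9to12", norms))
  # undecidable inputs flag the record rather than guessing
  expect_true(is.na(classify_cognitive_impairment_cohort(NA, FALSE, "9to12", norms)))
  expect_true(is.na(classify_cognitive_impairment_cohort(85, NA, "9to12", norms)))
  # a low score decides impairment even when the diagnosis flag is unknown
  expect_true(classify_cognitive_impairment_cohort(70, NA, "9to12", norms))
  expect_error(
    classify_cognitive_impairment_cohort(85, FALSE, "9to12",
                                         norms[norms$education != "9to12", ]),
    "stratum"
  )
})

test_that("cohort rule is monotone non-increasing in the test score", {
  norms <- toy_norms()
  scores <- seq(70, 100, by = 0.5)
  cls <- classify_cognitive_impairment_cohort(scores, FALSE, "gt12", norms)
  expect_true(all(diff(as.integer(cls)) <= 0))
})

test_that("NHATS rule requires AD8 > 2 with a diagnosis, or two of three impaired domains", {
  expect_true(classify_cognitive_impairment_nhats(TRUE, 3, FALSE, FALSE, FALSE))
  # AD8 of exactly 2 is not > 2, and a single domain is not enough
  expect_false(classify_cognitive_impairment_nhats(TRUE, 2, TRUE, FALSE, FALSE))
  expect_true(classify_cognitive_impairment_nhats(FALSE, 0, TRUE, TRUE, FALSE))
  expect_true(is.na(classify_cognitive_impairment_nhats(NA, NA, NA, NA, NA)))
  # full enumeration against the written rule
  grid <- expand.grid(dx = c(TRUE, FALSE), ad8 = 0:8,
                      m = c(TRUE, FALSE), o = c(TRUE, FALSE), e = c(TRUE, FALSE))
  got <- classify_cognitive_impairment_nhats(grid$dx, grid$ad8, grid$m, grid$o, grid$e)
  want <- (grid$dx & grid$ad8 > 2) | (grid$m + grid$o + grid$e >= 2)
  expect_identical(got, want)
})

test_that("ADL impairment count is the number of difficulty flags", {
  expect_identical(count_adl_impairments(FALSE, FALSE, FALSE, FALSE), 0L)
  expect_identical(count_adl_impairments(TRUE, TRUE, TRUE, TRUE), 4L)
  expect_identical(count_adl_impairments(TRUE, FALSE, TRUE, FALSE), 2L)
  expect_true(is.na(count_adl_impairments(TRUE, NA, FALSE, FALSE)))
})

test_that("frailty component thresholds are strict and sex-specific", {
  comp <- function(...) frailty_components(...)
  # weakness: < 32 kg for men (31.9 qualifies, 32.0 does not)
  expect_true(comp("male", 0, 0, 25, 31.9, FALSE, 1, FALSE, FALSE)$weakness)
  expect_false(comp("male", 0, 0, 25, 32.0, FALSE, 1, FALSE, FALSE)$weakness)
  expect_true(comp("female", 0, 0, 25, 19.9, FALSE, 1, FALSE, FALSE)$weakness)
  # slowness: < 0.6 m/s for women; the boundary itself is not slow
  expect_false(comp("female", 0, 0, 25, 25, FALSE, 0.60, FALSE, FALSE)$slowness)
  expect_true(comp("female", 0, 0, 25, 25, FALSE, 0.59, FALSE, FALSE)$slowness)
  expect_true(comp("male", 0, 0, 25, 40, FALSE, 0.79, FALSE, FALSE)$slowness)
  # a walking aid makes a participant slow regardless of gait speed
  expect_true(comp("female", 0, 0, 25, 25, FALSE, 1.2, TRUE, FALSE)$slowness)
  # shrinking: BMI < 18.5 alone qualifies
  expect_true(comp("female", 0, 0, 18.4, 25, FALSE, 1, FALSE, FALSE)$shrinking)
  expect_false(comp("female", 4.9, 9.9, 18.5, 25, FALSE, 1, FALSE, FALSE)$shrinking)
  expect_true(comp("female", 5.0, 0, 25, 25, FALSE, 1, FALSE, FALSE)$shrinking)
  expect_true(comp("female", 0, 10, 25, 25, FALSE, 1, FALSE, FALSE)$shrinking)
  # missing input without a deciding criterion flags the component
  expect_true(is.na(comp("female", NA, 2, 25, 25, FALSE, 1, FALSE, FALSE)$shrinking))
})

test_that("sex-specific thresholds only move classifications in the documented direction", {
  # identical measurements: a man can be weak/slow where a woman is not, never
  # the reverse (female thresholds are lower)
  for (grip in c(15, 21, 25, 33)) {
    f <- frailty_components("female", 0, 0, 25, grip, FALSE, 1, FALSE, FALSE)$weakness
    m <- frailty_components("male", 0, 0, 25, grip, FALSE, 1, FALSE, FALSE)$weakness
    expect_true(m >= f)
  }
  for (gait in c(0.5, 0.65, 0.75, 0.9)) {
    f <- frailty_components("female", 0, 0, 25, 25, FALSE, gait, FALSE, FALSE)$slowness
    m <- frailty_components("male", 0, 0, 25, 40, FALSE, gait, FALSE, FALSE)$slowness
    expect_true(m >= f)
  }
})

test_that("frailty category matches the brute-force rule table over all 32 component patterns", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  count <- rowSums(grid)
  got <- classify_phenotypic_frailty(count)
  want <- vapply(count, function(k) {
    if (k == 0) "robust" else if (k == 1 || k == 2) "prefrail" else "frail"
  }, character(1))
  expect_identical(as.character(got), want)
  expect_error(classify_phenotypic_frailty(6), "0..5")
})

test_that("category never moves toward robust as components accumulate", {
  sev <- c(robust = 1, prefrail = 2, frail = 3)
  cats <- sev[as.character(classify_phenotypic_frailty(0:5))]
  expect_true(all(diff(cats) >= 0))
})

test_that("comorbidity counting uses the sex-specific vocabulary", {
  expect_identical(count_comorbidities("", "female"), 0L)
  expect_identical(
    count_comorbidities("anemia;diabetes;breast_cancer", "female"), 3L)
  # breast cancer is not on the male list
  expect_identical(count_comorbidities("breast_cancer", "male"), 0L)
  expect_identical(count_comorbidities("prostate_cancer", "male"), 1L)
  expect_warning(count_comorbidities("gout", "male"), "vocabulary")
  expect_identical(lengths(default_condition_lists()),
                   c(female = 12L, male = 11L))
})

test_that("norms are estimated from the 65-69 normative band per stratum", {
  set.seed(1)
  d <- data.frame(
    age = c(rep(66, 40), rep(67, 40), rep(68, 40), rep(80, 30)),
    education = rep(c("lt9", "9to12", "gt12"), 50),
    cog_score = 0
  )
  d$cog_score <- ifelse(d$education == "lt9", rnorm(150, 85, 5),
                        ifelse(d$education == "9to12", rnorm(150, 90, 5),
                               rnorm(150, 95, 5)))
  older <- d$age > 69
  d$cog_score[older] <- d$cog_score[older] - 30  # must not contaminate norms
  norms <- estimate_reference_norms(d)
  inband <- d[!older, ]
  for (e in c("lt9", "9to12", "gt12")) {
    expect_equal(norms$mean[norms$education == e],
                 mean(inband$cog_score[inband$education == e]))
    expect_equal(norms$sd[norms$education == e],
                 sd(inband$cog_score[inband$education == e]))
  }
})

test_that("phenotype_cohort derives every status and flags incomplete rows", {
  d <- rbind(
    make_participant(id = "a", dementia_dx = TRUE, adl_walk = TRUE,
                     conditions = "diabetes;anemia"),
    make_participant(id = "b", grip_kg = 15, gait_ms = 0.5, poor_energy = TRUE),
    make_participant(id = "c", cog_score = NA, dementia_dx = NA)
  )
  ph <- phenotype_cohort(d, norms = toy_norms())
  expect_identical(ph$cognitively_impaired, c(1L, 0L, NA_integer_))
  expect_identical(ph$n_adl_impairments, c(1L, 0L, 0L))
  expect_identical(as.character(ph$frailty_category), c("robust", "frail", "robust"))
  expect_identical(ph$comorbidity_count, c(2L, 0L, 0L))
  expect_identical(ph$phenotype_complete, c(TRUE, TRUE, FALSE))
  expect_identical(levels(ph$race), c("nh_white", "nh_black", "other"))
})
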