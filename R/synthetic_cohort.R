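# Synthetic Medicare-like cohort generator with known exposure -> mediator ->
# cost structure, plus the Monte-Carlo g-computation oracle that evaluates the
# true total/direct/indirect decomposition on the generative model itself.

#' Generative parameters for a synthetic cohort
#'
#' Builds the full parameter set for one sex-specific cohort. Three presets
#' are shipped:
#' * `"medicare-like"`: cognitive-impairment prevalence near 12% (women) / 11%
#'   (men), right-skewed gamma costs with a log-linear mean, mediators (ADL
#'   count, phenotypic frailty, CFI) positively associated with both
#'   cognitive impairment and costs, and death over 36 months enriched in the
#'   impaired group (0.32 vs 0.11);
#' * `"null"`: exposure randomized and all exposure effects (direct and
#'   through mediators) set to zero;
#' * `"pure-mediation"`: exposure randomized, no direct cost effect, mediator
#'   shifts retained — the exposure affects cost only through the mediators.
#'
#' @param preset `"medicare-like"`, `"null"`, or `"pure-mediation"`.
#' @param sex `"female"` or `"male"`.
#' @param n Cohort size (defaults to the sex-specific analytic sizes 4318 /
#'   3847).
#' @param seed RNG seed for [generate_cohort()].
#' @param overrides Named list of parameter overrides applied on top of the
#'   preset.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(preset = c("medicare-like", "null", "pure-mediation"),
                              sex = c("female", "male"), n = NULL, seed = 1L,
                              overrides = list()) {
  preset <- match.arg(preset)
  sex <- match.arg(sex)
  female <- sex == "female"
  p <- list(
    sex = sex,
    n = if (is.null(n)) if (female) 4318L else 3847L else as.integer(n),
    seed = as.integer(seed),
    age_mean = if (female) 80.0 else 78.4,
    age_sd = if (female) 6.5 else 6.0,
    age_min = 65,
    race_probs = if (female) c(nh_white = 0.766, nh_black = 0.197, other = 0.037)
                 else c(nh_white = 0.809, nh_black = 0.138, other = 0.053),
    region_probs = c(midwest = 0.30, northeast = 0.20, south = 0.30, west = 0.20),
    edu_probs = c(lt9 = 0.15, `9to12` = 0.45, gt12 = 0.40),
    norms = reference_norms_table(c("lt9", "9to12", "gt12"),
                                  c(86, 90, 94), c(6, 6, 6)),
    ci_prevalence = if (female) 0.121 else 0.109,
    ci_age_slope = 0.10,
    ci_race_logor = c(nh_white = 0, nh_black = 0.80, other = 0.60),
    p_dementia_dx_given_ci = 0.5,
    adl_cutpoints = if (female) c(-0.18, -0.95, -1.99, -2.90)
                    else c(-0.92, -1.65, -2.62, -3.50),
    adl_ci_shift = 1.4,
    frailty_probs = if (female)
      c(shrinking = 0.14, weakness = 0.42, poor_energy = 0.38,
        slowness = 0.52, low_activity = 0.40)
    else
      c(shrinking = 0.10, weakness = 0.33, poor_energy = 0.30,
        slowness = 0.40, low_activity = 0.30),
    frailty_ci_shift = 0.65,
    cfi_mean = if (female) c(unexposed = 0.16, exposed = 0.21)
               else c(unexposed = 0.15, exposed = 0.18),
    cfi_phi = if (female) c(unexposed = 52, exposed = 33)
              else c(unexposed = 50, exposed = 29),
    condition_probs = if (female)
      c(anemia = 0.20, chronic_kidney_disease = 0.12, copd = 0.12,
        depression = 0.15, diabetes = 0.18, heart_failure = 0.10,
        ischemic_heart_disease = 0.20, osteoporosis = 0.25,
        colorectal_cancer = 0.04, lung_cancer = 0.02,
        breast_cancer = 0.08, endometrial_cancer = 0.02)
    else
      c(anemia = 0.18, chronic_kidney_disease = 0.14, copd = 0.14,
        depression = 0.10, diabetes = 0.20, heart_failure = 0.12,
        ischemic_heart_disease = 0.28, osteoporosis = 0.08,
        colorectal_cancer = 0.05, lung_cancer = 0.03,
        prostate_cancer = 0.12),
    condition_age_slope = 0.08,
    hcc_intercept = 0.55, hcc_per_condition = 0.22, hcc_ci_shift = 0.30,
    hcc_age_slope = 0.02, hcc_noise_shape = 2, hcc_noise_scale = 0.15,
    p_death = if (female) c(unexposed = 0.106, exposed = 0.326)
              else c(unexposed = 0.109, exposed = 0.316),
    beta0 = if (female) log(6200) else log(6500),
    beta_ci = if (female) 0.18 else 0.20,
    beta_age = 0.02,
    beta_race = c(nh_white = 0, nh_black = 0.08, other = 0.05),
    beta_region = c(midwest = 0, northeast = 0.05, south = -0.04, west = 0.02),
    beta_comorb = 0.13,
    beta_adl = c(0, 0.15, 0.30, 0.45, 0.60),
    beta_frailty = c(robust = 0, prefrail = 0.12, frail = 0.30),
    beta_cfi = 1.8,
    gamma_shape = 0.5
  )
  if (preset %in% c("null", "pure-mediation")) {
    # exposure randomized: no age/race dependence of CI status
    p$ci_age_slope <- 0
    p$ci_race_logor[] <- 0
    p$beta_ci <- 0
  }
  if (preset == "null") {
    p$adl_ci_shift <- 0
    p$frailty_ci_shift <- 0
    p$cfi_mean["exposed"] <- p$cfi_mean["unexposed"]
    p$cfi_phi["exposed"] <- p$cfi_phi["unexposed"]
    p$hcc_ci_shift <- 0
    p$p_death[] <- 0.15
  }
  p$preset <- preset
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p <- modifyList(p, overrides)
  }
  validate_generative_params(p)
  structure(p, class = "generative_params")
}

#' Validate generative parameters
#'
#' @param p Parameter list as from [generative_params()].
#' @return `p` invisibly; errors describe the first violated constraint.
#' @export
validate_generative_params <- function(p) {
  stopifnot(is.list(p))
  if (!p$sex %in% c("female", "male")) stop("sex must be 'female' or 'male'")
  if (p$n < 1) stop("n must be positive")
  if (p$gamma_shape <= 0) stop("gamma_shape must be positive")
  probs <- c(p$ci_prevalence, p$race_probs, p$region_probs, p$edu_probs,
             p$frailty_probs, p$condition_probs, p$p_death,
             p$p_dementia_dx_given_ci)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(p$cfi_mean <= 0 | p$cfi_mean >= 1)) stop("cfi_mean must lie in (0, 1)")
  if (any(p$cfi_phi <= 0)) stop("cfi_phi must be positive")
  if (is.unsorted(rev(p$adl_cutpoints), strictly = FALSE)) {
    stop("adl_cutpoints must be non-increasing (cumulative ordinal thresholds)")
  }
  if (length(p$beta_adl) != 5L) stop("beta_adl needs one value per ADL count 0..4")
  if (length(p$beta_frailty) != 3L) stop("beta_frailty needs robust/prefrail/frail values")
  if (p$age_sd <= 0) stop("age_sd must be positive")
  invisible(p)
}

# Intercept of the CI logistic model solving for the target prevalence over
# the age (truncated normal) x race mixture.
.ci_intercept <- function(p) {
  prev_at <- function(b0) {
    sum(vapply(seq_along(p$race_probs), function(r) {
      p$race_probs[r] * integrate(function(a) {
        dnorm(a, p$age_mean, p$age_sd) / (1 - pnorm(p$age_min, p$age_mean, p$age_sd)) *
          plogis(b0 + p$ci_age_slope * (a - 80) + p$ci_race_logor[r])
      }, p$age_min, p$age_mean + 12 * p$age_sd)$value
    }, numeric(1)))
  }
  uniroot(function(b0) prev_at(b0) - p$ci_prevalence, c(-15, 10), tol = 1e-10)$root
}

# Shared mediator draws given CI status (vectors of length n).
.draw_mediators <- function(p, ci) {
  n <- length(ci)
  u <- runif(n)
  p_ge <- matrix(vapply(p$adl_cutpoints, function(tau) {
    plogis(tau + p$adl_ci_shift * ci)
  }, numeric(n)), nrow = n)
  adl_count <- as.integer(rowSums(u < p_ge))
  comp <- matrix(vapply(p$frailty_probs, function(pj) {
    rbinom(n, 1L, plogis(qlogis(pj) + p$frailty_ci_shift * ci))
  }, integer(n)), nrow = n, dimnames = list(NULL, names(p$frailty_probs)))
  cfi_mu <- ifelse(ci == 1, p$cfi_mean["exposed"], p$cfi_mean["unexposed"])
  cfi_phi <- ifelse(ci == 1, p$cfi_phi["exposed"], p$cfi_phi["unexposed"])
  cfi <- rbeta(n, cfi_mu * cfi_phi, (1 - cfi_mu) * cfi_phi)
  list(adl_count = adl_count, components = comp,
       component_count = as.integer(rowSums(comp)), cfi = cfi)
}

# Expected annualized cost given exposure, mediators, and covariates.
.cost_mean <- function(p, ci, adl_count, frailty_count, cfi, age, race, region,
                       comorb) {
  frail_idx <- ifelse(frailty_count == 0L, 1L, ifelse(frailty_count <= 2L, 2L, 3L))
  exp(p$beta0 + p$beta_ci * ci + p$beta_age * (age - 80) +
        unname(p$beta_race[race]) + unname(p$beta_region[region]) +
        p$beta_comorb * comorb + p$beta_adl[adl_count + 1L] +
        unname(p$beta_frailty[frail_idx]) + p$beta_cfi * cfi)
}

# Covariate draws shared by generator and oracle.
.draw_covariates <- function(p, n) {
  u <- runif(n, pnorm(p$age_min, p$age_mean, p$age_sd), 1)
  age <- qnorm(u, p$age_mean, p$age_sd)
  race <- sample(names(p$race_probs), n, replace = TRUE, prob = p$race_probs)
  region <- sample(names(p$region_probs), n, replace = TRUE, prob = p$region_probs)
  cond <- matrix(vapply(seq_along(p$condition_probs), function(j) {
    rbinom(n, 1L, plogis(qlogis(p$condition_probs[j]) +
                           p$condition_age_slope * (age - 80)))
  }, integer(n)), nrow = n, dimnames = list(NULL, names(p$condition_probs)))
  list(age = age, race = race, region = region, condition_matrix = cond,
       comorb = as.integer(rowSums(cond)))
}

#' Generate a synthetic Medicare-like cohort
#'
#' Draws one participant table from the generative model: demographics;
#' cognitive-impairment status from a logistic model in age and race
#' (calibrated by numerical integration so the marginal prevalence hits the
#' preset target); mediators conditional on impairment status (ADL count via
#' an ordinal logit, the five frailty components via per-component Bernoulli
#' draws, CFI via a beta distribution with an impairment-shifted mean);
#' death and truncated follow-up; and cumulative THC whose annualized value
#' is gamma with a log-linear mean. Raw component measures (grip strength,
#' gait speed, weight loss, cognitive test score, ...) are emitted consistent
#' with the drawn statuses, so [phenotype_cohort()] recovers them exactly.
#'
#' @param params A [generative_params()] object.
#' @return A participant-level `data.frame` with the cohort CSV column
#'   contract, carrying attributes `reference_norms` (the norms used for the
#'   test-score rule), `generative_params`, and `truth` (the drawn statuses,
#'   for validation).
#' @export
generate_cohort <- function(params) {
  p <- validate_generative_params(params)
  set.seed(p$seed)
  n <- p$n

  cov <- .draw_covariates(p, n)
  age <- cov$age; race <- cov$race; region <- cov$region
  education <- sample(names(p$edu_probs), n, replace = TRUE, prob = p$edu_probs)

  b0 <- .ci_intercept(p)
  ci <- rbinom(n, 1L, plogis(b0 + p$ci_age_slope * (age - 80) +
                               unname(p$ci_race_logor[race])))

  # cognitive measures consistent with CI status under the test-score rule
  dementia_dx <- ci == 1L & runif(n) < p$p_dementia_dx_given_ci
  idx <- match(education, p$norms$education)
  cutoff <- p$norms$mean[idx] - 1.5 * p$norms$sd[idx]
  cog_score <- cutoff + 0.5 + abs(rnorm(n, 0, 6))        # unimpaired scores
  low <- ci == 1L & !dementia_dx
  cog_score[low] <- pmax(0, cutoff[low] - 0.5 - abs(rnorm(sum(low), 0, 4)))
  ad8 <- ifelse(dementia_dx, 3L + rbinom(n, 5L, 0.4), rbinom(n, 2L, 0.4))
  n_dom <- ifelse(ci == 1L, 2L + rbinom(n, 1L, 0.5), rbinom(n, 1L, 0.25))
  dom_memory <- n_dom >= 1L
  dom_orientation <- n_dom >= 2L
  dom_executive <- n_dom >= 3L

  med <- .draw_mediators(p, ci)

  # ADL flags: assign the drawn count to a random subset of the four items
  rk <- matrix(runif(4L * n), n, 4L)
  rk <- t(apply(rk, 1L, rank))
  adl_flags <- rk <= med$adl_count
  colnames(adl_flags) <- c("adl_walk", "adl_climb", "adl_transfer", "adl_bathe")

  # raw frailty measures consistent with the drawn component flags
  comp <- med$components == 1L
  female <- p$sex == "female"
  weight_loss_pct <- ifelse(comp[, "shrinking"], runif(n, 5, 12), runif(n, 0, 4.5))
  weight_loss_lb <- round(weight_loss_pct * 1.6, 1)
  bmi <- runif(n, 20, 32)
  grip_thr <- if (female) 20 else 32
  grip_kg <- ifelse(comp[, "weakness"], grip_thr - runif(n, 1, 10),
                    grip_thr + runif(n, 1, 15))
  gait_thr <- if (female) 0.6 else 0.8
  slowness <- comp[, "slowness"]
  gait_ms <- ifelse(slowness, gait_thr - runif(n, 0.05, 0.35),
                    gait_thr + runif(n, 0.05, 0.60))
  walking_aid <- slowness & runif(n) < 0.3

  cond_mat <- cov$condition_matrix
  conditions <- apply(cond_mat, 1L, function(z) {
    paste(colnames(cond_mat)[z == 1L], collapse = ";")
  })
  hcc_score <- round(pmax(0, p$hcc_intercept + p$hcc_per_condition * cov$comorb +
                            p$hcc_ci_shift * ci + p$hcc_age_slope * (age - 80) +
                            rgamma(n, p$hcc_noise_shape, scale = p$hcc_noise_scale)), 3)

  p_die <- ifelse(ci == 1L, p$p_death["exposed"], p$p_death["unexposed"])
  died <- rbinom(n, 1L, p_die) == 1L
  followup_months <- ifelse(died, pmax(runif(n, 0, 36), 1e-3), 36)

  mu <- .cost_mean(p, ci, med$adl_count, med$component_count, med$cfi,
                   age, race, region, cov$comorb)
  annualized <- rgamma(n, shape = p$gamma_shape, rate = p$gamma_shape / mu)
  cumulative_cost <- annualized * followup_months / 12

  out <- data.frame(
    id = sprintf("%s%05d", substr(p$sex, 1, 1), seq_len(n)),
    sex = p$sex, age = age, race = race, region = region, education = education,
    cog_score = round(cog_score, 1), dementia_dx = dementia_dx,
    ad8 = as.integer(pmin(ad8, 8L)),
    dom_memory = dom_memory, dom_orientation = dom_orientation,
    dom_executive = dom_executive,
    weight_loss_pct = round(weight_loss_pct, 2),
    weight_loss_lb = weight_loss_lb, bmi = round(bmi, 1),
    grip_kg = round(grip_kg, 2), poor_energy = comp[, "poor_energy"],
    gait_ms = round(gait_ms, 3), walking_aid = walking_aid,
    never_walks_and_no_mvpa = comp[, "low_activity"],
    adl_walk = adl_flags[, 1], adl_climb = adl_flags[, 2],
    adl_transfer = adl_flags[, 3], adl_bathe = adl_flags[, 4],
    conditions = conditions, hcc_score = hcc_score, cfi = med$cfi,
    followup_months = followup_months, died = died,
    cumulative_cost = cumulative_cost,
    continuously_enrolled = TRUE,
    stringsAsFactors = FALSE
  )
  attr(out, "reference_norms") <- p$norms
  attr(out, "generative_params") <- p
  attr(out, "truth") <- data.frame(
    ci = ci, n_adl_impairments = med$adl_count,
    frailty_component_count = med$component_count, comorbidity_count = cov$comorb
  )
  out
}

#' Generative-truth decomposition by Monte-Carlo g-computation
#'
#' Evaluates the decomposition directly on the generative model, without any
#' fitting. The true total is `E[cost | do(CI = 1)] - E[cost | do(CI = 0)]`
#' with mediators drawn from their CI-conditional laws and covariates from
#' the population law. The true direct effect repeats the contrast with the
#' mediators in the explanatory set held at their CI = 0 law (mediators
#' outside the set still follow CI). The indirect effect is the difference.
#' Expected (not sampled) costs are averaged, so the Monte-Carlo error
#' reflects covariate/mediator variation only.
#'
#' @param params A [generative_params()] object.
#' @param explanatory Explanatory set to attribute, as in
#'   [decomposition_spec()].
#' @param n_mc Monte-Carlo draws (>= 10000).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return List of class `oracle_decomposition`: `true_total`, `true_direct`,
#'   `true_indirect`, `mc_se` (SE of the total contrast), and per-component
#'   SEs.
#' @export
decomposition_oracle <- function(params, explanatory = "all_three",
                                 n_mc = 100000L, seed = 1L) {
  p <- validate_generative_params(params)
  if (n_mc < 10000L) stop("n_mc must be at least 10000")
  expl_cols <- .explanatory_columns(explanatory)
  set.seed(as.integer(seed))
  cov <- .draw_covariates(p, n_mc)
  m1 <- .draw_mediators(p, rep(1L, n_mc))
  m0 <- .draw_mediators(p, rep(0L, n_mc))
  # mediators for the direct arm: set members at the CI = 0 law
  mix <- list(
    adl_count = if ("adl_category" %in% expl_cols) m0$adl_count else m1$adl_count,
    component_count = if ("frailty_category" %in% expl_cols) m0$component_count
                      else m1$component_count,
    cfi = if ("cfi" %in% expl_cols) m0$cfi else m1$cfi
  )
  mu_of <- function(ci, m) .cost_mean(p, ci, m$adl_count, m$component_count,
                                      m$cfi, cov$age, cov$race, cov$region,
                                      cov$comorb)
  d_total <- mu_of(1, m1) - mu_of(0, m0)
  d_direct <- mu_of(1, mix) - mu_of(0, m0)
  structure(list(
    true_total = mean(d_total),
    true_direct = mean(d_direct),
    true_indirect = mean(d_total - d_direct),
    mc_se = sd(d_total) / sqrt(n_mc),
    mc_se_direct = sd(d_direct) / sqrt(n_mc),
    mc_se_indirect = sd(d_total - d_direct) / sqrt(n_mc),
    explanatory = explanatory, n_mc = n_mc
  ), class = "oracle_decomposition")
}

#' @export
print.oracle_decomposition <- function(x, ...) {
  cat(sprintf("Generative truth [%s]: total %.1f, direct %.1f, indirect %.1f (mc_se %.1f)\n",
              x$explanatory, x$true_total, x$true_direct, x$true_indirect, x$mc_se))
  invisible(x)
}

#' Write a cohort CSV with a provenance sidecar
#'
#' Writes the cohort table and a `<path>.provenance.json` recording the
#' generative parameters, seed, and an MD5 content hash of the CSV.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  p <- attr(cohort, "generative_params")
  prov <- list(
    n = nrow(cohort),
    seed = if (!is.null(p)) p$seed else NA,
    params = if (!is.null(p)) unclass(p)[setdiff(names(p), "norms")] else NULL,
    md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
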