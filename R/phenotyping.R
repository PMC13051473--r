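# Harmonized phenotype construction: cognitive impairment, ADL impairment
# counts, the five-component phenotypic frailty classification, and the
# comorbidity count against a sex-specific condition vocabulary.

#' Default condition vocabulary for the comorbidity count
#'
#' Chronic conditions commonly associated with higher healthcare costs,
#' counted from claims-based condition flags. Three cancers are sex-specific,
#' so women are scored against 12 conditions and men against 11.
#'
#' @return A named list with elements `female` and `male`, each a character
#'   vector of condition labels.
#' @export
#' @examples
#' lengths(default_condition_lists())
default_condition_lists <- function() {
  shared <- c(
    "anemia", "chronic_kidney_disease", "copd", "depression", "diabetes",
    "heart_failure", "ischemic_heart_disease", "osteoporosis",
    "colorectal_cancer", "lung_cancer"
  )
  list(
    female = c(shared, "breast_cancer", "endometrial_cancer"),
    male   = c(shared, "prostate_cancer")
  )
}

#' Education strata used throughout the package
#' @keywords internal
.education_levels <- c("lt9", "9to12", "gt12")

#' Construct a cognitive test norms table
#'
#' Norms are the education-stratified mean and standard deviation of the
#' cognitive test score among adults aged 65-69, the reference against which
#' the 1.5-SD impairment cutoff is applied.
#'
#' @param education Character vector of education strata; must contain each of
#'   `"lt9"`, `"9to12"`, `"gt12"` exactly once.
#' @param mean,sd Numeric vectors of stratum means and standard deviations
#'   (test points); `sd` must be strictly positive.
#' @return A `data.frame` with columns `education`, `mean`, `sd`.
#' @export
#' @examples
#' reference_norms_table(c("lt9", "9to12", "gt12"), c(86, 90, 94), c(6, 6, 6))
reference_norms_table <- function(education, mean, sd) {
  education <- as.character(education)
  if (!setequal(education, .education_levels) ||
      length(education) != 3L) {
    stop("norms must contain each education stratum ('lt9', '9to12', 'gt12') exactly once")
  }
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("norm SD must be strictly positive in every stratum")
  }
  if (any(!is.finite(mean))) stop("norm means must be finite")
  data.frame(education = education, mean = as.numeric(mean), sd = as.numeric(sd),
             stringsAsFactors = FALSE)
}

#' Estimate cognitive test norms from a cohort
#'
#' Computes the stratified mean and SD of the cognitive test score among
#' participants aged 65-69 (the youngest age band, chosen to limit inclusion
#' of prevalent dementia), per education stratum.
#'
#' @param data Cohort data frame with columns `age`, `education`, `cog_score`.
#' @param age_range Inclusive age band used as the normative sample.
#' @return A norms table as from [reference_norms_table()].
#' @export
estimate_reference_norms <- function(data, age_range = c(65, 69)) {
  sub <- data[!is.na(data$age) & data$age >= age_range[1] & data$age <= age_range[2] &
                !is.na(data$cog_score) & !is.na(data$education), , drop = FALSE]
  mu <- vapply(.education_levels, function(e) {
    s <- sub$cog_score[sub$education == e]
    if (length(s) < 2L) return(NA_real_)
    mean(s)
  }, numeric(1))
  sg <- vapply(.education_levels, function(e) {
    s <- sub$cog_score[sub$education == e]
    if (length(s) < 2L) return(NA_real_)
    sd(s)
  }, numeric(1))
  if (anyNA(mu) || anyNA(sg)) {
    stop("cannot estimate norms: fewer than 2 normative participants in stratum ",
         paste(.education_levels[is.na(mu) | is.na(sg)], collapse = ", "))
  }
  reference_norms_table(.education_levels, mu, sg)
}

#' Classify cognitive impairment (cohort test-score rule)
#'
#' A participant is cognitively impaired if they carry a self- or
#' proxy-reported clinician diagnosis of dementia, or if their cognitive test
#' score lies at least 1.5 SD below the education-stratified normative mean
#' (boundary inclusive: `score <= mean - 1.5 * sd`).
#'
#' @param cog_score Numeric test score; `NA` allowed when `dementia_dx` known.
#' @param dementia_dx Logical diagnosis flag.
#' @param education Education stratum per participant.
#' @param norms Norms table from [reference_norms_table()] or
#'   [estimate_reference_norms()].
#' @param n_sd Number of SDs below the stratum mean defining the cutoff.
#' @return Logical vector; `NA` where the rule is undecidable from the
#'   available inputs (record flagged for exclusion downstream).
#' @export
#' @examples
#' norms <- reference_norms_table(c("lt9", "9to12", "gt12"), c(90, 90, 90), c(6, 6, 6))
#' classify_cognitive_impairment_cohort(81.0, FALSE, "9to12", norms)  # TRUE (boundary)
classify_cognitive_impairment_cohort <- function(cog_score, dementia_dx, education,
                                                 norms, n_sd = 1.5) {
  n <- max(length(cog_score), length(dementia_dx), length(education))
  cog_score <- rep_len(as.numeric(cog_score), n)
  dementia_dx <- rep_len(as.logical(dementia_dx), n)
  education <- rep_len(as.character(education), n)
  missing_stratum <- setdiff(unique(education[!is.na(education)]), norms$education)
  if (length(missing_stratum)) {
    stop("norms table lacks education stratum: ", paste(missing_stratum, collapse = ", "))
  }
  idx <- match(education, norms$education)
  cutoff <- norms$mean[idx] - n_sd * norms$sd[idx]
  below <- cog_score <= cutoff
  out <- ifelse(!is.na(dementia_dx) & dementia_dx, TRUE,
                ifelse(!is.na(below) & below, TRUE,
                       ifelse(!is.na(dementia_dx) & !is.na(below), FALSE, NA)))
  # dx unknown but score clearly above cutoff cannot rule impairment out
  out[is.na(dementia_dx) & !is.na(below) & !below] <- NA
  out[is.na(cog_score) & !is.na(dementia_dx) & !dementia_dx] <- NA
  as.logical(out)
}

#' Classify cognitive impairment (NHATS-style rule)
#'
#' Impaired if a reported dementia diagnosis is accompanied by a proxy AD8
#' score greater than 2, or if at least two of three cognitive domains
#' (memory, orientation, executive function) are flagged impaired.
#'
#' @param dementia_dx Logical diagnosis flag.
#' @param ad8 Integer 0-8 proxy informant score.
#' @param dom_memory,dom_orientation,dom_executive Logical domain-impairment
#'   flags (precomputed; domain scoring is out of scope here).
#' @return Logical vector; `NA` where all inputs are missing.
#' @export
classify_cognitive_impairment_nhats <- function(dementia_dx, ad8, dom_memory,
                                                dom_orientation, dom_executive) {
  n <- max(length(dementia_dx), length(ad8), length(dom_memory),
           length(dom_orientation), length(dom_executive))
  dementia_dx <- rep_len(as.logical(dementia_dx), n)
  ad8 <- rep_len(as.numeric(ad8), n)
  doms <- cbind(rep_len(as.logical(dom_memory), n),
                rep_len(as.logical(dom_orientation), n),
                rep_len(as.logical(dom_executive), n))
  arm1 <- !is.na(dementia_dx) & dementia_dx & !is.na(ad8) & ad8 > 2
  ndom <- rowSums(doms)
  arm2 <- !is.na(ndom) & ndom >= 2
  out <- arm1 | arm2
  undecidable <- !out & (is.na(dementia_dx) | is.na(ad8)) & is.na(ndom)
  out[undecidable] <- NA
  out
}

#' Count ADL functional impairments
#'
#' Counts self-reported difficulty with four activities of daily living:
#' walking a few blocks, climbing steps, transferring bed to chair, and
#' bathing or showering.
#'
#' @param adl_walk,adl_climb,adl_transfer,adl_bathe Logical difficulty flags.
#' @return Integer 0-4; `NA` where any flag is missing.
#' @export
count_adl_impairments <- function(adl_walk, adl_climb, adl_transfer, adl_bathe) {
  m <- cbind(as.logical(adl_walk), as.logical(adl_climb),
             as.logical(adl_transfer), as.logical(adl_bathe))
  as.integer(rowSums(m))
}

#' Evaluate the five phenotypic frailty components
#'
#' Applies the harmonized component definitions:
#' * shrinking: weight loss >= 5% or >= 10 lb, or BMI < 18.5 kg/m^2;
#' * weakness: grip strength < 32 kg (men) / < 20 kg (women);
#' * poor energy: as reported;
#' * slowness: gait speed < 0.8 m/s (men) / < 0.6 m/s (women), or use of a
#'   walking aid;
#' * low activity: never walks for exercise and no moderate/vigorous activity.
#'
#' Inequalities are strict exactly as the thresholds are stated.
#'
#' @param sex `"female"` or `"male"` per participant.
#' @param weight_loss_pct,weight_loss_lb Recent weight loss (% and pounds).
#' @param bmi Body-mass index, kg/m^2.
#' @param grip_kg Grip strength, kg.
#' @param poor_energy Logical self-reported poor energy.
#' @param gait_ms Usual gait speed, m/s.
#' @param walking_aid Logical use of a walking aid.
#' @param never_walks_and_no_mvpa Logical low-physical-activity flag.
#' @return A data frame of five logical columns (`shrinking`, `weakness`,
#'   `poor_energy`, `slowness`, `low_activity`); rows with a missing input
#'   carry `NA` in the affected component.
#' @export
frailty_components <- function(sex, weight_loss_pct, weight_loss_lb, bmi, grip_kg,
                               poor_energy, gait_ms, walking_aid,
                               never_walks_and_no_mvpa) {
  sex <- as.character(sex)
  bad_sex <- !is.na(sex) & !sex %in% c("female", "male")
  if (any(bad_sex)) stop("sex must be 'female' or 'male'")
  male <- sex == "male"
  # three-way OR: NA-safe (any TRUE decides even when another input is missing)
  shrinking <- (weight_loss_pct >= 5) | (weight_loss_lb >= 10) | (bmi < 18.5)
  grip_thr <- ifelse(male, 32, 20)
  weakness <- grip_kg < grip_thr
  gait_thr <- ifelse(male, 0.8, 0.6)
  slowness <- (gait_ms < gait_thr) | as.logical(walking_aid)
  data.frame(
    shrinking = as.logical(shrinking),
    weakness = as.logical(weakness),
    poor_energy = as.logical(poor_energy),
    slowness = as.logical(slowness),
    low_activity = as.logical(never_walks_and_no_mvpa)
  )
}

#' Classify phenotypic frailty from the component count
#'
#' @param count Integer 0-5 number of positive frailty components.
#' @return Factor with levels `robust` (0 components, referent), `prefrail`
#'   (1-2), `frail` (>= 3).
#' @export
#' @examples
#' classify_phenotypic_frailty(c(0, 2, 3))
classify_phenotypic_frailty <- function(count) {
  count <- as.integer(count)
  if (any(!is.na(count) & (count < 0L | count > 5L))) {
    stop("frailty component count must lie in 0..5")
  }
  out <- ifelse(count == 0L, "robust", ifelse(count <= 2L, "prefrail", "frail"))
  factor(out, levels = c("robust", "prefrail", "frail"))
}

#' Count comorbid conditions against a sex-specific vocabulary
#'
#' @param conditions Character vector; per participant, condition labels
#'   separated by `;` (empty string or `NA` means no conditions).
#' @param sex `"female"` or `"male"` per participant.
#' @param condition_lists Named list of sex-specific vocabularies, as from
#'   [default_condition_lists()].
#' @param warn_unknown Warn once when a label outside the union vocabulary is
#'   seen.
#' @return Integer count of conditions intersected with the participant's
#'   sex-specific list.
#' @export
count_comorbidities <- function(conditions, sex,
                                condition_lists = default_condition_lists(),
                                warn_unknown = TRUE) {
  sex <- as.character(sex)
  conditions <- as.character(conditions)
  conditions[is.na(conditions)] <- ""
  split_cond <- strsplit(conditions, ";", fixed = TRUE)
  vocab <- unique(unlist(condition_lists))
  unknown <- setdiff(unique(unlist(split_cond)), c(vocab, ""))
  if (length(unknown) && warn_unknown) {
    warning("condition labels outside the configured vocabulary: ",
            paste(unknown, collapse = ", "))
  }
  vapply(seq_along(split_cond), function(i) {
    lst <- condition_lists[[sex[i]]]
    if (is.null(lst)) return(NA_integer_)
    length(intersect(split_cond[[i]], lst))
  }, integer(1))
}

#' Derive all phenotypes for a cohort table
#'
#' Adds the derived analysis variables to a participant-level cohort table:
#' `cognitively_impaired` (0/1), `n_adl_impairments` and `adl_category`
#' (factor `0`..`4`, reference `0`), `frailty_component_count` and
#' `frailty_category` (factor `robust`/`prefrail`/`frail`), and
#' `comorbidity_count`. Factor codings for `race` (reference `nh_white`) and
#' `region` (reference first alphabetically) are set here so downstream model
#' matrices are reproducible. A `phenotype_complete` flag marks rows with all
#' required phenotype inputs observed; incomplete rows carry `NA` phenotypes
#' and are excluded before modelling by [apply_exclusions()].
#'
#' @param data Cohort data frame (see the package vignette for the column
#'   contract).
#' @param norms Optional norms table. When `NULL`, a `"reference_norms"`
#'   attribute on `data` is used if present (synthetic cohorts carry one);
#'   otherwise norms are estimated from the cohort's 65-69-year-olds.
#' @param rule Cognitive-impairment rule: `"cohort"` (test score vs. norms) or
#'   `"nhats"` (AD8/domain rule).
#' @param condition_lists Sex-specific condition vocabulary.
#' @return `data` with derived columns appended.
#' @export
phenotype_cohort <- function(data, norms = NULL, rule = c("cohort", "nhats"),
                             condition_lists = default_condition_lists()) {
  rule <- match.arg(rule)
  if (is.null(norms)) norms <- attr(data, "reference_norms")
  if (rule == "cohort" && is.null(norms)) norms <- estimate_reference_norms(data)

  ci <- if (rule == "cohort") {
    classify_cognitive_impairment_cohort(data$cog_score, data$dementia_dx,
                                         data$education, norms)
  } else {
    classify_cognitive_impairment_nhats(data$dementia_dx, data$ad8,
                                        data$dom_memory, data$dom_orientation,
                                        data$dom_executive)
  }

  n_adl <- count_adl_impairments(data$adl_walk, data$adl_climb,
                                 data$adl_transfer, data$adl_bathe)
  comp <- frailty_components(data$sex, data$weight_loss_pct, data$weight_loss_lb,
                             data$bmi, data$grip_kg, data$poor_energy,
                             data$gait_ms, data$walking_aid,
                             data$never_walks_and_no_mvpa)
  comp_count <- as.integer(rowSums(comp))
  frailty_cat <- classify_phenotypic_frailty(comp_count)
  comorb <- count_comorbidities(data$conditions, data$sex, condition_lists)

  data$cognitively_impaired <- as.integer(ci)
  data$n_adl_impairments <- n_adl
  data$adl_category <- factor(n_adl, levels = 0:4)
  data$frailty_component_count <- comp_count
  data$frailty_category <- frailty_cat
  data$comorbidity_count <- comorb
  data$race <- factor(as.character(data$race),
                      levels = c("nh_white", "nh_black", "other"))
  data$region <- factor(as.character(data$region))

  required <- cbind(ci = !is.na(ci), adl = !is.na(n_adl),
                    frail = !is.na(comp_count), comorb = !is.na(comorb),
                    demo = !is.na(data$age) & !is.na(data$race) &
                      !is.na(data$region) & !is.na(data$education),
                    cfi = if (!is.null(data$cfi)) !is.na(data$cfi) else TRUE)
  data$phenotype_complete <- as.logical(apply(required, 1, all))
  attr(data, "reference_norms") <- norms
  data
}
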