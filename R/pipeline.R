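# End-to-end analysis orchestration: exclusion cascade, descriptive tables,
# the sex-stratified decomposition suite with both sensitivity analyses, and
# report/figure output.

#' Format a percentage to one decimal
#'
#' Display convention used by every report table: percentages to one decimal,
#' dollars to the nearest integer. Raw precision is preserved in the JSON
#' report.
#'
#' @param x Percentage value(s) on the 0-100 scale.
#' @param digits Decimals to print.
#' @return Character vector.
#' @export
#' @examples
#' fmt_pct(100 * 1236 / 17282)  # "7.2"
fmt_pct <- function(x, digits = 1) {
  formatC(round(x, digits), format = "f", digits = digits)
}

#' Apply the exclusion cascade
#'
#' Drops records with missing phenotype inputs first, then records not
#' continuously enrolled in fee-for-service Medicare (the
#' `continuously_enrolled` flag), in that order; the counts are
#' order-dependent and the order is recorded in the report. Rows lacking the
#' enrollment flag count as enrollment failures.
#'
#' @param data Raw cohort rows, phenotyped with [phenotype_cohort()] so that
#'   `phenotype_complete` is available (if absent it is computed here).
#' @param norms Passed to [phenotype_cohort()] when phenotyping is needed.
#' @return A list with `data` (the analytic rows) and `report` (class
#'   `exclusion_report`: `n_initial`, `n_missing_excluded`,
#'   `n_enrollment_excluded`, `n_analytic`, one-decimal percentages, and
#'   per-reason counts).
#' @export
apply_exclusions <- function(data, norms = NULL) {
  if (is.null(data$phenotype_complete)) {
    data <- phenotype_cohort(data, norms = norms)
  }
  n_initial <- nrow(data)
  complete <- data$phenotype_complete %in% TRUE &
    !is.na(data$followup_months) & data$followup_months > 0 &
    !is.na(data$cumulative_cost)
  n_missing <- sum(!complete)
  kept <- data[complete, , drop = FALSE]
  enrolled <- if (is.null(kept$continuously_enrolled)) {
    rep(FALSE, nrow(kept))
  } else {
    kept$continuously_enrolled %in% TRUE
  }
  n_enroll <- sum(!enrolled)
  analytic <- kept[enrolled, , drop = FALSE]
  report <- structure(list(
    n_initial = n_initial,
    n_missing_excluded = n_missing,
    n_enrollment_excluded = n_enroll,
    n_analytic = nrow(analytic),
    pct_missing_excluded = fmt_pct(100 * n_missing / n_initial),
    pct_enrollment_excluded = fmt_pct(100 * n_enroll / n_initial),
    per_reason = c(missing_phenotype = n_missing, not_enrolled = n_enroll)
  ), class = "exclusion_report")
  stopifnot(report$n_analytic ==
              report$n_initial - report$n_missing_excluded - report$n_enrollment_excluded)
  list(data = analytic, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade:\n",
      "  initial            ", x$n_initial, "\n",
      "  missing data       ", x$n_missing_excluded, " (", x$pct_missing_excluded, "%)\n",
      "  not FFS-enrolled   ", x$n_enrollment_excluded, " (", x$pct_enrollment_excluded, "%)\n",
      "  analytic cohort    ", x$n_analytic, "\n", sep = "")
  invisible(x)
}

.mean_sd_fmt <- function(x, digits = 1) {
  if (!length(x) || all(is.na(x))) return("-")
  if (length(x) == 1L) return(sprintf(paste0("%.", digits, "f (-)"), x))
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean(x, na.rm = TRUE),
          sd(x, na.rm = TRUE))
}

.n_pct_fmt <- function(k, n) {
  if (n == 0L) return("-")
  sprintf("%d (%s)", k, fmt_pct(100 * k / n))
}

# One descriptive column for a group of rows.
.describe_group <- function(d) {
  n <- nrow(d)
  if (n == 0L) {
    return(c(n = "0", setNames(rep("-", 14),
                               c("age", "race_nh_white", "race_nh_black", "race_other",
                                 "comorbidity_count", "hcc_score", "adl_none", "adl_1_2",
                                 "adl_3_4", "phenotypic_frailty", "cfi", "annualized_thc",
                                 "died", "prevalence_pct"))))
  }
  c(n = as.character(n),
    age = .mean_sd_fmt(d$age),
    race_nh_white = .n_pct_fmt(sum(d$race == "nh_white", na.rm = TRUE), n),
    race_nh_black = .n_pct_fmt(sum(d$race == "nh_black", na.rm = TRUE), n),
    race_other = .n_pct_fmt(sum(d$race == "other", na.rm = TRUE), n),
    comorbidity_count = .mean_sd_fmt(d$comorbidity_count),
    hcc_score = if (is.null(d$hcc_score)) "-" else .mean_sd_fmt(d$hcc_score),
    adl_none = .n_pct_fmt(sum(d$n_adl_impairments == 0L, na.rm = TRUE), n),
    adl_1_2 = .n_pct_fmt(sum(d$n_adl_impairments %in% 1:2, na.rm = TRUE), n),
    adl_3_4 = .n_pct_fmt(sum(d$n_adl_impairments %in% 3:4, na.rm = TRUE), n),
    phenotypic_frailty = .n_pct_fmt(sum(d$frailty_category == "frail", na.rm = TRUE), n),
    cfi = if (is.null(d$cfi)) "-" else .mean_sd_fmt(d$cfi, 2),
    annualized_thc = .mean_sd_fmt(d$annualized_thc, 0),
    died = .n_pct_fmt(sum(d$died %in% TRUE), n),
    prevalence_pct = "")
}

#' Descriptive characteristics by sex and cognitive-impairment status
#'
#' @param data Phenotyped, costed analytic rows.
#' @return A data frame with one row per characteristic and one column per
#'   sex-by-impairment group, plus a `prevalence` attribute giving the
#'   one-decimal impairment prevalence per sex.
#' @export
describe_cohort <- function(data) {
  groups <- list()
  prevalence <- c()
  for (s in intersect(c("female", "male"), unique(as.character(data$sex)))) {
    d <- data[data$sex == s, , drop = FALSE]
    n_ci <- sum(d$cognitively_impaired == 1L, na.rm = TRUE)
    prevalence[s] <- fmt_pct(100 * n_ci / nrow(d))
    groups[[paste0(s, "_ci")]] <-
      .describe_group(d[d$cognitively_impaired %in% 1L, , drop = FALSE])
    groups[[paste0(s, "_no_ci")]] <-
      .describe_group(d[d$cognitively_impaired %in% 0L, , drop = FALSE])
  }
  out <- as.data.frame(groups, stringsAsFactors = FALSE)
  out <- cbind(characteristic = rownames(out), out)
  rownames(out) <- NULL
  attr(out, "prevalence") <- prevalence
  out
}

#' Default analysis configuration
#'
#' @return A named list of configuration defaults; see the vignette for the
#'   full schema.
#' @export
default_analysis_config <- function() {
  list(
    cohort_csv = NULL,
    preset = "medicare-like",
    n_female = 4318L, n_male = 3847L, seed = 20230101L,
    rule = "cohort",
    norms = NULL,
    bootstrap = list(n_reps = 1000L, seed = 1L, stratified_by_sex = TRUE),
    zero_rule = "floor", zero_value = 1,
    explanatory_sets = c("functional_impairments", "phenotypic_frailty",
                         "cfi", "all_three"),
    base_covariates = c("age", "race", "region", "comorbidity_count"),
    sensitivity_hcc = TRUE,
    sensitivity_pooling = TRUE,
    inflation = NULL,      # list(year_column =, table = list(year = multiplier))
    output_dir = NULL,
    make_figure = TRUE
  )
}

#' Load an analysis configuration from YAML
#'
#' @param path YAML file; keys override [default_analysis_config()].
#' @return Configuration list.
#' @export
load_analysis_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_analysis_config(), user)
  cfg
}

# Decomposition suite for one sex's rows.
.decompose_suite <- function(d, cfg, base_covariates) {
  lapply(setNames(cfg$explanatory_sets, cfg$explanatory_sets), function(set) {
    spec <- decomposition_spec(
      explanatory = set, base_covariates = base_covariates,
      n_reps = cfg$bootstrap$n_reps, seed = cfg$bootstrap$seed,
      stratified_by_sex = cfg$bootstrap$stratified_by_sex
    )
    res <- bootstrap_decomposition(d, spec, zero_rule = cfg$zero_rule,
                                   zero_value = cfg$zero_value)
    stopifnot(abs(res$direct + res$indirect - res$total) < 1e-9)
    res
  })
}

.result_rows <- function(res, model, sex) {
  ci <- function(x) if (is.null(x)) c(NA_real_, NA_real_) else x
  data.frame(
    model = model, sex = sex,
    component = c("total", "direct", "indirect"),
    estimate = c(res$total, res$direct, res$indirect),
    ci_low = c(ci(res$ci_total)[1], ci(res$ci_direct)[1], ci(res$ci_indirect)[1]),
    ci_high = c(ci(res$ci_total)[2], ci(res$ci_direct)[2], ci(res$ci_indirect)[2]),
    share_pct = c(NA, NA, if (res$share_defined) round(res$indirect_share, 1) else NA),
    stringsAsFactors = FALSE
  )
}

#' Run the full cost-decomposition analysis
#'
#' Executes, from a configuration list or YAML path: cohort loading (CSV) or
#' synthetic generation (preset), the exclusion cascade, phenotyping,
#' costing, sex-stratified descriptive tables, the four-way decomposition
#' suite with bootstrap CIs, sensitivity analysis A (CMS-HCC score replacing
#' the comorbidity count), and sensitivity analysis B (sex-pooled estimates
#' with equal and size-proportional weights). Optionally writes
#' `table2.csv`, `table3.csv`, `report.json`, `exclusions.json`, and
#' `fig1.png` to `output_dir`.
#'
#' @param config Configuration list (see [default_analysis_config()]) or a
#'   YAML path.
#' @return A list of class `analysis_report`: `exclusions`, `table2`,
#'   `table3` (long data frame), `decompositions` (nested results),
#'   `sensitivity_hcc`, `pooled`, and `prevalence`.
#' @export
run_analysis <- function(config = list()) {
  if (is.character(config)) config <- load_analysis_config(config)
  cfg <- modifyList(default_analysis_config(), config)
  if ("education" %in% cfg$base_covariates) {
    stop("education cannot be a model covariate: it is part of the ",
         "cognitive-impairment definition")
  }

  if (!is.null(cfg$cohort)) {
    raw <- cfg$cohort
  } else if (!is.null(cfg$cohort_csv)) {
    raw <- read.csv(cfg$cohort_csv, stringsAsFactors = FALSE)
  } else {
    pieces <- list()
    if (cfg$n_female > 0) {
      pieces$female <- generate_cohort(generative_params(cfg$preset, "female",
                                                         cfg$n_female,
                                                         seed = cfg$seed))
    }
    if (cfg$n_male > 0) {
      pieces$male <- generate_cohort(generative_params(cfg$preset, "male",
                                                       cfg$n_male,
                                                       seed = cfg$seed + 1L))
    }
    raw <- do.call(rbind, unname(pieces))
    attr(raw, "reference_norms") <-
      generative_params(cfg$preset, "female", 10, seed = 1)$norms
  }

  norms <- cfg$norms
  if (is.list(norms) && !is.data.frame(norms)) {
    norms <- reference_norms_table(names(norms),
                                   vapply(norms, `[[`, numeric(1), "mean"),
                                   vapply(norms, `[[`, numeric(1), "sd"))
  }
  phen <- phenotype_cohort(raw, norms = norms, rule = cfg$rule)
  excl <- apply_exclusions(phen)
  analytic <- excl$data
  if (nrow(analytic) == 0L) {
    stop("no analytic rows remain after exclusions; nothing to model")
  }
  if (!is.null(cfg$inflation)) {
    tab <- inflation_table(as.integer(names(cfg$inflation$table)),
                           unlist(cfg$inflation$table))
    analytic <- add_annualized_costs(analytic,
                                     year_column = cfg$inflation$year_column,
                                     table = tab)
  } else {
    analytic <- add_annualized_costs(analytic)
  }

  table2 <- describe_cohort(analytic)
  sexes <- intersect(c("female", "male"), unique(as.character(analytic$sex)))
  decomp <- list(); sens_hcc <- list()
  table3 <- NULL
  for (s in sexes) {
    d <- analytic[analytic$sex == s, , drop = FALSE]
    decomp[[s]] <- .decompose_suite(d, cfg, cfg$base_covariates)
    for (set in names(decomp[[s]])) {
      table3 <- rbind(table3, .result_rows(decomp[[s]][[set]], set, s))
    }
    if (isTRUE(cfg$sensitivity_hcc) && !is.null(d$hcc_score)) {
      hcc_cov <- replace(cfg$base_covariates,
                         cfg$base_covariates == "comorbidity_count", "hcc_score")
      sens_hcc[[s]] <- .decompose_suite(d, cfg, hcc_cov)
    }
  }

  pooled <- NULL
  if (isTRUE(cfg$sensitivity_pooling) && all(c("female", "male") %in% sexes)) {
    pooled <- lapply(setNames(names(decomp$female), names(decomp$female)),
                     function(set) {
      list(equal = pool_sexes(decomp$female[[set]], decomp$male[[set]], "equal"),
           by_n = pool_sexes(decomp$female[[set]], decomp$male[[set]], "by_n"))
    })
  }

  report <- structure(list(
    exclusions = excl$report,
    prevalence = attr(table2, "prevalence"),
    table2 = table2,
    table3 = table3,
    decompositions = decomp,
    sensitivity_hcc = if (length(sens_hcc)) sens_hcc else NULL,
    pooled = pooled,
    config = cfg
  ), class = "analysis_report")

  if (!is.null(cfg$output_dir)) {
    write_analysis_report(report, cfg$output_dir, make_figure = cfg$make_figure)
  }
  report
}

# Strip non-serializable pieces for JSON output.
.result_json <- function(res) {
  keep <- c("total", "direct", "indirect", "indirect_share", "share_defined",
            "explanatory", "ci_total", "ci_direct", "ci_indirect", "n_failed",
            "n_obs")
  r <- unclass(res)[intersect(keep, names(res))]
  r
}

#' Write an analysis report to disk
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param make_figure Emit the stacked-bar decomposition figure (`fig1.png`)
#'   when the png device is available.
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir, make_figure = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  write.csv(report$table3, file.path(dir, "table3.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(report$exclusions),
                       file.path(dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  js <- list(
    prevalence = as.list(report$prevalence),
    exclusions = unclass(report$exclusions),
    decompositions = lapply(report$decompositions, function(by_sex) {
      lapply(by_sex, .result_json)
    }),
    sensitivity_hcc = if (!is.null(report$sensitivity_hcc)) {
      lapply(report$sensitivity_hcc, function(by_sex) lapply(by_sex, .result_json))
    },
    pooled = if (!is.null(report$pooled)) {
      lapply(report$pooled, function(w) lapply(w, .result_json))
    }
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(make_figure) && isTRUE(unname(capabilities("png")))) {
    fig <- plot_decomposition(report)
    ggplot2::ggsave(file.path(dir, "fig1.png"), fig, width = 8, height = 5,
                    dpi = 150)
  }
  invisible(dir)
}

#' Stacked-bar figure of the decomposition suite
#'
#' Direct and indirect components of the incremental THC of cognitive
#' impairment, one bar per explanatory model, faceted by sex.
#'
#' @param report An `analysis_report`.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(report) {
  d <- report$table3[report$table3$component %in% c("direct", "indirect"), ]
  d$component <- factor(d$component, levels = c("indirect", "direct"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$estimate,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Incremental annualized THC (2023 USD/yr)",
      fill = NULL,
      title = "Incremental costs of cognitive impairment: direct vs. indirect"
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.analysis_report <- function(x, ...) {
  print(x$exclusions)
  cat("Cognitive-impairment prevalence:",
      paste(names(x$prevalence), paste0(x$prevalence, "%"), collapse = "; "), "\n")
  cat("\nDecomposition suite (dollars/year):\n")
  print(x$table3, row.names = FALSE)
  invisible(x)
}
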