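# Difference-method decomposition of the incremental cost of cognitive
# impairment into direct and indirect components, with stratified percentile
# bootstrap confidence intervals and sex-pooled estimates.

#' Map an explanatory-set name to its analysis columns
#' @keywords internal
.explanatory_columns <- function(set) {
  switch(set,
         functional_impairments = "adl_category",
         phenotypic_frailty = "frailty_category",
         cfi = "cfi",
         all_three = c("adl_category", "frailty_category", "cfi"),
         stop("unknown explanatory set: ", set))
}

#' Specify a decomposition analysis
#'
#' The decomposition contrasts a base model (exposure + base covariates)
#' against the base model further adjusted for an explanatory set of
#' candidate mediators: ADL functional impairments (categorical 0-4),
#' phenotypic frailty (robust/prefrail/frail), the continuous claims-based
#' frailty index (CFI), or all three jointly.
#'
#' @param explanatory One of `"functional_impairments"`,
#'   `"phenotypic_frailty"`, `"cfi"`, `"all_three"`.
#' @param base_covariates Covariates of the base model (demographics +
#'   comorbidity burden by default).
#' @param outcome,exposure Outcome and binary exposure columns.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Bootstrap RNG seed.
#' @param stratified_by_sex Resample within sex strata when a `sex` column is
#'   present (all primary analyses are sex-stratified, so this matters only
#'   for pooled-data runs).
#' @return An object of class `decomposition_spec`.
#' @export
decomposition_spec <- function(explanatory = c("functional_impairments",
                                               "phenotypic_frailty", "cfi",
                                               "all_three"),
                               base_covariates = c("age", "race", "region",
                                                   "comorbidity_count"),
                               outcome = "annualized_thc",
                               exposure = "cognitively_impaired",
                               n_reps = 1000L, seed = 1L,
                               stratified_by_sex = TRUE) {
  explanatory <- match.arg(explanatory)
  expl_cols <- .explanatory_columns(explanatory)
  overlap <- intersect(expl_cols, base_covariates)
  if (length(overlap)) {
    stop("explanatory terms overlap the base covariates: ",
         paste(overlap, collapse = ", "))
  }
  if (n_reps < 2L) stop("n_reps must be at least 2")
  structure(list(explanatory = explanatory, expl_cols = expl_cols,
                 base_covariates = as.character(base_covariates),
                 outcome = outcome, exposure = exposure,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 stratified_by_sex = isTRUE(stratified_by_sex)),
            class = "decomposition_spec")
}

#' Assemble a decomposition result from its total and direct components
#'
#' The indirect component is defined by subtraction (`total - direct`), so
#' additivity `direct + indirect = total` holds exactly by construction. The
#' indirect share is `100 * indirect / total`, reported as undefined (NA,
#' with `share_defined = FALSE`) when the total is not positive.
#'
#' @param total Incremental cost from the base model, dollars/year.
#' @param direct Incremental cost from the explanatory-adjusted model.
#' @param explanatory Optional label of the explanatory set.
#' @return An object of class `decomposition_result`.
#' @export
#' @examples
#' decomposition_result(6883, 4642)  # indirect 2241, share 32.6%
decomposition_result <- function(total, direct, explanatory = NA_character_) {
  indirect <- total - direct
  share_defined <- is.finite(total) && total > 0
  structure(list(total = total, direct = direct, indirect = indirect,
                 indirect_share = if (share_defined) 100 * indirect / total else NA_real_,
                 share_defined = share_defined,
                 explanatory = explanatory,
                 ci_total = NULL, ci_direct = NULL, ci_indirect = NULL),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" (%.0f, %.0f)", ci[1], ci[2])
  cat("Decomposition", if (!is.na(x$explanatory)) paste0("[", x$explanatory, "]"), "\n")
  cat(sprintf("  total    %8.0f%s\n", x$total, fmt_ci(x$ci_total)))
  cat(sprintf("  direct   %8.0f%s\n", x$direct, fmt_ci(x$ci_direct)))
  cat(sprintf("  indirect %8.0f%s\n", x$indirect, fmt_ci(x$ci_indirect)))
  if (x$share_defined) {
    cat(sprintf("  indirect share %.1f%% of total\n", x$indirect_share))
  } else {
    cat("  indirect share undefined (total <= 0)\n")
  }
  invisible(x)
}

# Point decomposition on prebuilt matrices; returns c(total, direct).
# start_b/start_a warm-start the IRLS (used by the bootstrap).
.decompose_mats <- function(Xb, Xa, y, exposure, start_b = NULL, start_a = NULL) {
  fb <- .gamma_fit_mat(Xb, y, strict_rank = FALSE, start = start_b)
  fa <- .gamma_fit_mat(Xa, y, strict_rank = FALSE, start = start_a)
  total <- .marginal_means_mat(Xb, fb$coefficients, exposure)["incremental"]
  direct <- .marginal_means_mat(Xa, fa$coefficients, exposure)["incremental"]
  c(total = unname(total), direct = unname(direct))
}

# Prepare outcome + matrices shared by decompose and the bootstrap.
.prep_decomposition <- function(data, spec, zero_rule, zero_value) {
  base_spec <- cost_model_spec(spec$outcome, spec$exposure, spec$base_covariates)
  adj_spec <- cost_model_spec(spec$outcome, spec$exposure,
                              c(spec$base_covariates, spec$expl_cols))
  y_raw <- data[[spec$outcome]]
  if (is.null(y_raw)) stop("outcome column '", spec$outcome, "' not found")
  if (anyNA(y_raw)) stop("outcome contains missing values; exclude first")
  z <- .handle_zeros(y_raw, zero_rule, zero_value)
  data <- data[z$keep, , drop = FALSE]
  list(y = z$y[z$keep],
       Xb = .build_design(base_spec, data),
       Xa = .build_design(adj_spec, data),
       sex = if (spec$stratified_by_sex && !is.null(data$sex)) {
         as.character(data$sex)
       } else {
         rep("all", nrow(data))
       },
       n = nrow(data), n_zero = z$n_zero)
}

#' Decompose the incremental cost of cognitive impairment
#'
#' Fits the base gamma/log model and the explanatory-adjusted model, takes
#' the marginally standardized incremental cost from each (total and direct,
#' respectively), and attributes the remainder to the explanatory set
#' (indirect, by subtraction).
#'
#' @param data Phenotyped, costed cohort rows (typically one sex).
#' @param spec A [decomposition_spec()].
#' @param zero_rule,zero_value Zero-cost handling, as in [fit_cost_glm()].
#' @return A [decomposition_result()] without intervals; see
#'   [bootstrap_decomposition()] for CIs.
#' @export
decompose_costs <- function(data, spec, zero_rule = "floor", zero_value = 1) {
  stopifnot(inherits(spec, "decomposition_spec"))
  prep <- .prep_decomposition(data, spec, zero_rule, zero_value)
  est <- .decompose_mats(prep$Xb, prep$Xa, prep$y, spec$exposure)
  res <- decomposition_result(unname(est["total"]), unname(est["direct"]),
                              spec$explanatory)
  res$n_obs <- prep$n
  res
}

#' Decomposition with percentile-bootstrap confidence intervals
#'
#' Resamples participants with replacement (within sex strata when the data
#' carry a `sex` column and the spec asks for stratification), refits both
#' models per replicate, and reports 2.5th/97.5th percentile intervals for
#' the total, direct, and indirect components. The indirect interval comes
#' from replicate-wise `total - direct`, preserving their within-replicate
#' correlation. Replicates whose fits fail are dropped and counted; a warning
#' is raised when more than 5% are dropped.
#'
#' Per-replicate seeds are drawn once from the spec seed, so results are
#' reproducible and independent of evaluation order.
#'
#' @inheritParams decompose_costs
#' @param conf Interval coverage (default 0.95).
#' @return A [decomposition_result()] with `ci_total`, `ci_direct`,
#'   `ci_indirect`, the replicate matrix (`replicates`), and the failed
#'   replicate count (`n_failed`).
#' @export
bootstrap_decomposition <- function(data, spec, zero_rule = "floor",
                                    zero_value = 1, conf = 0.95) {
  stopifnot(inherits(spec, "decomposition_spec"))
  prep <- .prep_decomposition(data, spec, zero_rule, zero_value)
  fb <- .gamma_fit_mat(prep$Xb, prep$y)
  fa <- .gamma_fit_mat(prep$Xa, prep$y)
  est <- c(
    total = unname(.marginal_means_mat(prep$Xb, fb$coefficients,
                                       spec$exposure)["incremental"]),
    direct = unname(.marginal_means_mat(prep$Xa, fa$coefficients,
                                        spec$exposure)["incremental"])
  )

  strata <- split(seq_len(prep$n), prep$sex)
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_reps)

  reps <- matrix(NA_real_, nrow = spec$n_reps, ncol = 2,
                 dimnames = list(NULL, c("total", "direct")))
  for (r in seq_len(spec$n_reps)) {
    set.seed(rep_seeds[r])
    idx <- unlist(lapply(strata, function(ii) {
      ii[sample.int(length(ii), length(ii), replace = TRUE)]
    }), use.names = FALSE)
    reps[r, ] <- tryCatch(
      .decompose_mats(prep$Xb[idx, , drop = FALSE],
                      prep$Xa[idx, , drop = FALSE],
                      prep$y[idx], spec$exposure,
                      start_b = fb$coefficients, start_a = fa$coefficients),
      error = function(e) c(NA_real_, NA_real_)
    )
  }
  ok <- !is.na(reps[, 1]) & !is.na(reps[, 2])
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * spec$n_reps) {
    warning(n_failed, " of ", spec$n_reps, " bootstrap replicates failed (> 5%)")
  }
  good <- reps[ok, , drop = FALSE]
  alpha <- (1 - conf) / 2
  probs <- c(alpha, 1 - alpha)
  res <- decomposition_result(unname(est["total"]), unname(est["direct"]),
                              spec$explanatory)
  res$ci_total <- unname(quantile(good[, "total"], probs))
  res$ci_direct <- unname(quantile(good[, "direct"], probs))
  res$ci_indirect <- unname(quantile(good[, "total"] - good[, "direct"], probs))
  res$replicates <- cbind(good, indirect = good[, "total"] - good[, "direct"])
  res$n_failed <- n_failed
  res$n_obs <- prep$n
  res$conf <- conf
  res
}

#' Pool sex-stratified decomposition results
#'
#' Combines female and male results component-wise as `w_f * x_f + w_m *
#' x_m`, with equal weights or weights proportional to sample size. When both
#' results carry bootstrap replicate matrices of equal length, intervals are
#' recomputed on the weighted replicates; otherwise interval endpoints are
#' weighted directly and the result is flagged approximate.
#'
#' @param res_f,res_m `decomposition_result`s for women and men from the same
#'   spec.
#' @param weights `"equal"` or `"by_n"`.
#' @param n_f,n_m Stratum sample sizes (required for `"by_n"`; taken from the
#'   results when present).
#' @return A pooled `decomposition_result`.
#' @export
pool_sexes <- function(res_f, res_m, weights = c("equal", "by_n"),
                       n_f = res_f$n_obs, n_m = res_m$n_obs) {
  weights_mode <- if (is.character(weights)) match.arg(weights) else "numeric"
  stopifnot(inherits(res_f, "decomposition_result"),
            inherits(res_m, "decomposition_result"))
  if (!identical(res_f$explanatory, res_m$explanatory)) {
    stop("cannot pool results from different explanatory sets")
  }
  w <- switch(weights_mode,
              equal = c(0.5, 0.5),
              by_n = {
                if (is.null(n_f) || is.null(n_m)) stop("by_n pooling needs n_f and n_m")
                c(n_f, n_m) / (n_f + n_m)
              },
              numeric = {
                if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-8) {
                  stop("numeric weights must be two values summing to 1")
                }
                as.numeric(weights)
              })
  out <- decomposition_result(w[1] * res_f$total + w[2] * res_m$total,
                              w[1] * res_f$direct + w[2] * res_m$direct,
                              res_f$explanatory)
  out$weights <- w
  have_reps <- !is.null(res_f$replicates) && !is.null(res_m$replicates) &&
    nrow(res_f$replicates) == nrow(res_m$replicates)
  if (have_reps) {
    pooled <- w[1] * res_f$replicates + w[2] * res_m$replicates
    probs <- c(0.025, 0.975)
    out$ci_total <- unname(quantile(pooled[, "total"], probs))
    out$ci_direct <- unname(quantile(pooled[, "direct"], probs))
    out$ci_indirect <- unname(quantile(pooled[, "indirect"], probs))
    out$replicates <- pooled
    out$ci_method <- "pooled_replicates"
  } else if (!is.null(res_f$ci_total) && !is.null(res_m$ci_total)) {
    out$ci_total <- w[1] * res_f$ci_total + w[2] * res_m$ci_total
    out$ci_direct <- w[1] * res_f$ci_direct + w[2] * res_m$ci_direct
    out$ci_indirect <- w[1] * res_f$ci_indirect + w[2] * res_m$ci_indirect
    out$ci_method <- "weighted_endpoints_approximate"
  }
  out$n_obs <- sum(c(res_f$n_obs, res_m$n_obs))
  out
}
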