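# Gamma log-link marginal cost models: model specification, IRLS fitting
# (via the standard weighted-least-squares GLM machinery), and recycled
# predictions ("margins") yielding covariate-standardized mean costs by
# cognitive-impairment status.

#' Specify a marginal cost model
#'
#' A cost model regresses annualized THC on a binary exposure (cognitive
#' impairment) plus covariates, with gamma variance and a log link. Covariate
#' codings follow column classes: numeric columns enter linearly, factor
#' columns as treatment-coded dummies against their first level (set by
#' [phenotype_cohort()]: race vs `nh_white`, region vs the alphabetically
#' first label, ADL category vs `0`, frailty vs `robust`).
#'
#' Education is rejected as a covariate because educational level is part of
#' the cognitive-impairment definition.
#'
#' @param outcome Outcome column (dollars/year, strictly positive after the
#'   zero-handling rule).
#' @param exposure Binary 0/1 exposure column.
#' @param covariates Character vector of covariate columns (may be empty).
#' @return An object of class `cost_model_spec`.
#' @export
#' @examples
#' cost_model_spec()
cost_model_spec <- function(outcome = "annualized_thc",
                            exposure = "cognitively_impaired",
                            covariates = c("age", "race", "region",
                                           "comorbidity_count")) {
  covariates <- as.character(covariates)
  if ("education" %in% covariates) {
    stop("education cannot be a model covariate: it is part of the ",
         "cognitive-impairment definition")
  }
  if (exposure %in% covariates) stop("exposure duplicated among covariates")
  if (anyDuplicated(covariates)) stop("duplicated covariate terms")
  structure(list(outcome = outcome, exposure = exposure, covariates = covariates),
            class = "cost_model_spec")
}

#' @export
print.cost_model_spec <- function(x, ...) {
  cat("Gamma/log cost model: ", x$outcome, " ~ ", x$exposure,
      if (length(x$covariates)) paste(" +", paste(x$covariates, collapse = " + ")),
      "\n", sep = "")
  invisible(x)
}

# Apply the zero-cost rule; returns list(y, keep, n_zero).
.handle_zeros <- function(y, rule, zero_value) {
  n_zero <- sum(y == 0, na.rm = TRUE)
  keep <- rep(TRUE, length(y))
  if (n_zero > 0) {
    if (rule == "floor") {
      y[!is.na(y) & y == 0] <- zero_value
    } else if (rule == "shift") {
      y <- y + zero_value
    } else if (rule == "exclude") {
      keep <- is.na(y) | y > 0
    } else {
      stop("outcome contains ", n_zero,
           " zero value(s); the gamma family requires a strictly positive ",
           "outcome (choose a zero-handling rule)")
    }
  }
  list(y = y, keep = keep, n_zero = n_zero)
}

# Build the design matrix for a spec; exposure is always the second column.
.build_design <- function(spec, data) {
  f <- reformulate(c(spec$exposure, spec$covariates))
  X <- model.matrix(f, data)
  if (!spec$exposure %in% colnames(X)) {
    stop("exposure column '", spec$exposure,
         "' must be numeric 0/1 in the data")
  }
  X
}

# Core gamma/log IRLS fit on a prebuilt design matrix. Aliased columns that
# are identically zero in X (e.g., an empty factor level in a bootstrap
# resample) get coefficient 0; any other aliasing is an error.
.gamma_fit_mat <- function(X, y, epsilon = 1e-10, maxit = 100L,
                           strict_rank = TRUE, start = NULL) {
  if (!is.null(start) && anyNA(start)) start <- NULL
  fit <- suppressWarnings(
    glm.fit(X, y, family = Gamma(link = "log"), start = start,
            control = glm.control(epsilon = epsilon, maxit = maxit))
  )
  beta <- fit$coefficients
  if (anyNA(beta)) {
    nabs <- names(beta)[is.na(beta)]
    zero_cols <- colSums(abs(X[, nabs, drop = FALSE])) == 0
    if (strict_rank && !all(zero_cols)) {
      stop("rank-deficient design; aliased column(s): ",
           paste(nabs[!zero_cols], collapse = ", "))
    }
    if (!all(zero_cols)) stop("aliased non-empty column(s) in resample")
    beta[is.na(beta)] <- 0
  }
  if (!fit$converged) {
    stop("gamma GLM did not converge in ", maxit,
         " iterations (deviance ", format(fit$deviance), ")")
  }
  list(coefficients = beta, converged = fit$converged, iter = fit$iter,
       deviance = fit$deviance, fitted = fit$fitted.values)
}

#' Fit a gamma/log marginal cost model
#'
#' Coefficients solve the gamma score equations with log link by iteratively
#' reweighted least squares. The dispersion is the Pearson chi-square
#' statistic over `n - p`; it does not enter the point estimates or margins.
#'
#' @param spec A [cost_model_spec()].
#' @param data Phenotyped, costed cohort rows.
#' @param zero_rule How to handle zero outcomes before fitting: `"floor"`
#'   (replace 0 by `zero_value`, the default), `"shift"` (add `zero_value` to
#'   every outcome), `"exclude"` (drop zero rows), or `"none"` (error on
#'   zeros).
#' @param zero_value Dollar value used by the zero rule (default $1).
#' @param epsilon IRLS convergence tolerance on the relative deviance change.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `cost_glm` holding coefficients (log-dollar
#'   scale), dispersion, convergence metadata, the design matrix and outcome
#'   used, and the spec.
#' @export
fit_cost_glm <- function(spec, data, zero_rule = c("floor", "shift", "exclude", "none"),
                         zero_value = 1, epsilon = 1e-10, maxit = 100L) {
  zero_rule <- match.arg(zero_rule)
  stopifnot(inherits(spec, "cost_model_spec"))
  y_raw <- data[[spec$outcome]]
  if (is.null(y_raw)) stop("outcome column '", spec$outcome, "' not found")
  if (anyNA(y_raw)) stop("outcome contains missing values; exclude first")
  z <- .handle_zeros(y_raw, zero_rule, zero_value)
  data <- data[z$keep, , drop = FALSE]
  y <- z$y[z$keep]
  if (any(y <= 0)) stop("outcome must be strictly positive after zero handling")
  X <- .build_design(spec, data)
  if (nrow(X) <= ncol(X)) stop("more design columns than observations")
  fit <- .gamma_fit_mat(X, y, epsilon = epsilon, maxit = maxit)
  mu <- fit$fitted
  p <- ncol(X)
  dispersion <- sum((y - mu)^2 / mu^2) / (nrow(X) - p)
  structure(list(
    coefficients = fit$coefficients,
    dispersion = dispersion,
    converged = fit$converged,
    n_iterations = fit$iter,
    n_obs = nrow(X),
    n_zero_adjusted = z$n_zero,
    zero_rule = zero_rule,
    deviance = fit$deviance,
    spec = spec,
    X = X, y = y
  ), class = "cost_glm")
}

#' @export
print.cost_glm <- function(x, ...) {
  cat("Gamma/log GLM:", x$spec$outcome, "~", x$spec$exposure,
      if (length(x$spec$covariates)) paste("+", paste(x$spec$covariates, collapse = " + ")),
      "\n  n =", x$n_obs, " iterations =", x$n_iterations,
      " dispersion =", format(x$dispersion, digits = 4), "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Model-based standard errors of the coefficients
#'
#' Fisher-information standard errors using the Pearson dispersion; used for
#' parameter-recovery diagnostics (interval estimation for cost contrasts is
#' by bootstrap).
#'
#' @param fit A `cost_glm` fit.
#' @return Named numeric vector of standard errors.
#' @export
coef_se <- function(fit) {
  stopifnot(inherits(fit, "cost_glm"))
  mu <- as.vector(exp(fit$X %*% fit$coefficients))
  # log link, gamma variance: working weights are constant = 1/dispersion
  XtWX <- crossprod(fit$X) / fit$dispersion
  se <- sqrt(diag(solve(XtWX)))
  setNames(se, colnames(fit$X))
}

# Recycled predictions on a design matrix: exposure column forced to 1 and 0.
.marginal_means_mat <- function(X, beta, exposure) {
  X1 <- X; X1[, exposure] <- 1
  X0 <- X; X0[, exposure] <- 0
  m1 <- mean(exp(as.vector(X1 %*% beta)))
  m0 <- mean(exp(as.vector(X0 %*% beta)))
  c(mean_exposed = m1, mean_unexposed = m0, incremental = m1 - m0)
}

#' Marginally standardized mean costs by exposure status
#'
#' Recycled predictions: every participant's cost is predicted with exposure
#' forced to 1 and then to 0, and the predictions are averaged over the
#' (estimation or supplied) sample, yielding covariate-adjusted mean THC with
#' and without cognitive impairment. The incremental cost is their
#' difference, exactly.
#'
#' @param fit A `cost_glm` fit.
#' @param data Optional new cohort rows to standardize over (defaults to the
#'   estimation sample).
#' @return A list of class `marginal_means` with `mean_exposed`,
#'   `mean_unexposed` and `incremental` (dollars/year).
#' @export
marginal_means <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "cost_glm"))
  if (!fit$converged) stop("fit did not converge")
  X <- if (is.null(data)) fit$X else .build_design(fit$spec, data)
  expo <- X[, fit$spec$exposure]
  if (!all(expo %in% c(0, 1))) stop("exposure column must be binary 0/1")
  mm <- .marginal_means_mat(X, fit$coefficients, fit$spec$exposure)
  structure(list(mean_exposed = unname(mm["mean_exposed"]),
                 mean_unexposed = unname(mm["mean_unexposed"]),
                 incremental = unname(mm["incremental"])),
            class = "marginal_means")
}

#' @export
print.marginal_means <- function(x, ...) {
  cat(sprintf("Adjusted mean THC: exposed %.2f, unexposed %.2f, incremental %.2f $/yr\n",
              x$mean_exposed, x$mean_unexposed, x$incremental))
  invisible(x)
}
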