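# Death-truncated annualization and inflation standardization of cumulative
# total healthcare costs (THC).

#' Construct an inflation table
#'
#' Maps calendar year to a multiplier converting that year's dollars to 2023
#' dollars. The 2023 multiplier must be present and equal to 1, anchoring the
#' standardization.
#'
#' @param years Integer vector of calendar years.
#' @param multipliers Positive multipliers to 2023 dollars, parallel to
#'   `years`.
#' @return Named numeric vector (names = years).
#' @export
#' @examples
#' inflation_table(c(2019, 2023), c(1.18, 1))
inflation_table <- function(years, multipliers) {
  years <- as.integer(years)
  multipliers <- as.numeric(multipliers)
  if (length(years) != length(multipliers)) stop("years and multipliers must align")
  if (any(!is.finite(multipliers)) || any(multipliers <= 0)) {
    stop("inflation multipliers must be positive")
  }
  if (!2023L %in% years) stop("inflation table must contain the anchor year 2023")
  if (abs(multipliers[match(2023L, years)] - 1) > 1e-12) {
    stop("the 2023 multiplier must equal 1")
  }
  setNames(multipliers, years)
}

#' Standardize a cost to 2023 dollars
#'
#' @param cost Dollar amount(s), non-negative.
#' @param year Calendar year the cost was incurred in.
#' @param table Inflation table from [inflation_table()].
#' @return Cost in 2023 dollars.
#' @export
standardize_cost <- function(cost, year, table) {
  if (any(!is.na(cost) & cost < 0)) stop("costs must be non-negative")
  key <- as.character(as.integer(year))
  if (any(!key %in% names(table))) {
    stop("inflation table lacks year(s): ",
         paste(setdiff(unique(key), names(table)), collapse = ", "))
  }
  cost * unname(table[key])
}

#' Annualize cumulative costs with truncation at death
#'
#' Annualized THC is cumulative cost divided by observed follow-up in years.
#' Follow-up is 36 months for survivors and is truncated at death otherwise,
#' so decedents' costs are spread over their observed exposure only.
#'
#' @param cumulative_cost Cumulative THC in dollars, non-negative.
#' @param followup_months Observed follow-up, months in (0, 36].
#' @param died Logical death-during-follow-up flag.
#' @param validate Check the follow-up contract (survivors must have the full
#'   36 months; non-positive exposure cannot be annualized).
#' @return Annualized THC in dollars/year.
#' @export
#' @examples
#' annualize_cost(45000, 36, FALSE)  # 15000/yr
#' annualize_cost(10000, 12, TRUE)   # 10000/yr
annualize_cost <- function(cumulative_cost, followup_months, died, validate = TRUE) {
  if (validate) {
    if (any(!is.na(cumulative_cost) & cumulative_cost < 0)) {
      stop("cumulative costs must be non-negative")
    }
    bad_zero <- !is.na(followup_months) & followup_months <= 0
    if (any(bad_zero)) {
      stop("cannot annualize zero or negative follow-up (",
           sum(bad_zero), " record(s)); exclude these before costing")
    }
    if (any(!is.na(followup_months) & followup_months > 36)) {
      stop("follow-up exceeds the 36-month ascertainment window")
    }
    bad_alive <- !is.na(died) & !died & !is.na(followup_months) & followup_months != 36
    if (any(bad_alive)) {
      stop("survivors must have the full 36 months of follow-up (",
           sum(bad_alive), " record(s) violate this)")
    }
  }
  cumulative_cost / (followup_months / 12)
}

#' Add annualized, inflation-standardized costs to a cohort table
#'
#' Appends `followup_years` and `annualized_thc`. When `cost_columns` names
#' several component columns (hospital, SNF, outpatient, DME, HHC, ...) they
#' are summed into the cumulative cost first. When `year_column` and `table`
#' are supplied, cumulative costs are standardized to 2023 dollars before
#' annualization.
#'
#' @param data Cohort data frame with `followup_months` and `died`.
#' @param cost_columns Column name(s) holding cumulative cost (components).
#' @param year_column Optional column of cost-incurrence years.
#' @param table Optional inflation table (required with `year_column`).
#' @return `data` with `followup_years` and `annualized_thc` appended.
#' @export
add_annualized_costs <- function(data, cost_columns = "cumulative_cost",
                                 year_column = NULL, table = NULL) {
  missing_cols <- setdiff(cost_columns, names(data))
  if (length(missing_cols)) {
    stop("cost column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  cumulative <- if (length(cost_columns) == 1L) {
    data[[cost_columns]]
  } else {
    rowSums(data[cost_columns])
  }
  if (!is.null(year_column)) {
    if (is.null(table)) stop("an inflation table is required with year_column")
    cumulative <- standardize_cost(cumulative, data[[year_column]], table)
  }
  data$followup_years <- data$followup_months / 12
  data$annualized_thc <- annualize_cost(cumulative, data$followup_months, data$died)
  data
}
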