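# Capital annuitisation and direct overhead allocation.
#
# Hospital-wide shared costs (administration, security, laundry, catering,
# utilities) and capital items (buildings, vehicles, laboratory equipment)
# cannot be metered per patient. They are apportioned to the paediatric
# programme in one step ("direct allocation") by a space share or a
# patient-load share, and capital outlays are first converted to an
# equivalent annual cost with the annuity formula.

#' Annuity factor
#'
#' The present value of one currency unit per year for `years` years at
#' discount rate `rate`: `(1 - (1 + rate)^-years) / rate`, with the zero-rate
#' limit equal to `years`. Dividing a replacement cost by this factor gives
#' the equivalent annual cost of a capital item.
#'
#' @param rate Discount rate as a fraction per year (default 3%).
#' @param years Useful life in whole years (>= 1).
#' @return Dimensionless factor in years.
#' @export
#' @examples
#' annuity_factor(0.03, 40)  # ~23.11, buildings over 40 years at 3%
annuity_factor <- function(rate, years) {
  assert_scalar_number(rate, "rate", min = 0)
  assert_scalar_number(years, "years", min = 1, integerish = TRUE)
  if (rate == 0) return(as.numeric(years))
  (1 - (1 + rate)^(-years)) / rate
}

#' Define a capital asset
#'
#' @param asset_name Label.
#' @param replacement_cost Current replacement cost (currency, >= 0).
#' @param useful_life Useful life in whole years (>= 1). Conventional
#'   defaults in this setting: 40 years for buildings, 5 for vehicles and
#'   laboratory equipment.
#' @param category One of `building`, `vehicle`, `lab_equipment`.
#' @return A `capital_asset` list.
#' @export
capital_asset <- function(asset_name, replacement_cost, useful_life,
                          category = c("building", "vehicle", "lab_equipment")) {
  assert_scalar_number(replacement_cost, "replacement_cost", min = 0)
  assert_scalar_number(useful_life, "useful_life", min = 1, integerish = TRUE)
  structure(list(asset_name = asset_name,
                 replacement_cost = replacement_cost,
                 useful_life = as.integer(useful_life),
                 category = match.arg(category)),
            class = "capital_asset")
}

#' Equivalent annual cost of a capital asset
#'
#' Annuitises the replacement cost over the asset's useful life:
#' `replacement_cost / annuity_factor(rate, useful_life)`.
#'
#' @param asset A [capital_asset()].
#' @param rate Annual discount rate (default 3%).
#' @return Currency per year.
#' @export
equivalent_annual_cost <- function(asset, rate = 0.03) {
  stopifnot(inherits(asset, "capital_asset"))
  asset$replacement_cost / annuity_factor(rate, asset$useful_life)
}

#' Allocation basis and weight
#'
#' An allocation basis is a programme share of a facility total: floor space
#' of the paediatric section over total floor space (`space_share`), or
#' paediatric inpatient load over total admissions (`patient_load_share`).
#' `allocation_weight()` returns the fraction `numerator / denominator`.
#'
#' @param basis_kind `"space_share"` or `"patient_load_share"`.
#' @param numerator Programme measure (>= 0, <= denominator).
#' @param denominator Facility total (> 0).
#' @return `allocation_basis()`: a validated list; `allocation_weight()`:
#'   a fraction in `[0, 1]`.
#' @export
allocation_basis <- function(basis_kind = c("space_share", "patient_load_share"),
                             numerator, denominator) {
  basis_kind <- match.arg(basis_kind)
  assert_scalar_number(denominator, "denominator", min = .Machine$double.xmin)
  assert_scalar_number(numerator, "numerator", min = 0, max = denominator)
  structure(list(basis_kind = basis_kind, numerator = numerator,
                 denominator = denominator),
            class = "allocation_basis")
}

#' @rdname allocation_basis
#' @param basis An `allocation_basis`.
#' @export
allocation_weight <- function(basis) {
  stopifnot(inherits(basis, "allocation_basis"))
  basis$numerator / basis$denominator
}

#' Directly allocate an overhead ledger to a programme
#'
#' Applies one allocation weight per ledger line in a single step, ignoring
#' interactions between overhead departments. Each allocated amount is the
#' line amount times its weight; with all weights 1 the allocation equals
#' the ledger (conservation).
#'
#' @param ledger Named numeric vector of annual amounts (line item -> amount),
#'   or a data frame with columns `line_item` and `annual_amount`.
#' @param weights Named numeric vector of fractions in `[0, 1]`, covering
#'   every ledger line.
#' @return Named numeric vector of allocated annual amounts.
#' @export
#' @examples
#' allocate_overhead(c(administration = 1000, catering = 600),
#'                   c(administration = 0.25, catering = 0.2))
allocate_overhead <- function(ledger, weights) {
  if (is.data.frame(ledger)) {
    ledger <- setNames(ledger$annual_amount, ledger$line_item)
  }
  if (any(ledger < 0)) abort("ledger amounts must be >= 0")
  missing <- setdiff(names(ledger), names(weights))
  if (length(missing) > 0) {
    abort(paste0("no allocation weight for ledger line(s): ",
                 paste(missing, collapse = ", ")))
  }
  w <- weights[names(ledger)]
  if (any(w < 0 | w > 1)) abort("allocation weights must lie in [0, 1]")
  ledger * w
}

#' Per-bed-day overhead rate
#'
#' Converts an allocated annual overhead total into a "hotel" cost per
#' inpatient bed-day.
#'
#' @param allocated_total Allocated overhead, currency per year.
#' @param bed_days Programme bed-days per year (> 0).
#' @return Currency per bed-day.
#' @export
per_day_overhead_rate <- function(allocated_total, bed_days) {
  assert_scalar_number(allocated_total, "allocated_total", min = 0)
  assert_scalar_number(bed_days, "bed_days", min = .Machine$double.xmin)
  allocated_total / bed_days
}

#' Load overhead ledgers and asset registers from CSV
#'
#' `load_overhead_ledger()` reads columns `line_item`, `annual_amount`;
#' `load_asset_register()` reads columns `asset_name`, `replacement_cost`,
#' `useful_life`, `category` and returns a list of [capital_asset()]s.
#'
#' @param path CSV file path.
#' @return See details.
#' @export
load_overhead_ledger <- function(path) {
  tab <- readr::read_csv(path, col_types = "cd", progress = FALSE)
  if (!all(c("line_item", "annual_amount") %in% names(tab))) {
    abort("overhead ledger CSV must have columns line_item and annual_amount")
  }
  if (any(tab$annual_amount < 0)) abort("ledger amounts must be >= 0")
  setNames(tab$annual_amount, tab$line_item)
}

#' @rdname load_overhead_ledger
#' @export
load_asset_register <- function(path) {
  tab <- readr::read_csv(path, col_types = "cdic", progress = FALSE)
  required <- c("asset_name", "replacement_cost", "useful_life", "category")
  if (!all(required %in% names(tab))) {
    abort(paste0("asset register CSV must have columns ",
                 paste(required, collapse = ", ")))
  }
  purrr::pmap(tab, function(asset_name, replacement_cost, useful_life, category) {
    capital_asset(asset_name, replacement_cost, useful_life, category)
  })
}

#' Annuitised, allocated capital cost per programme patient
#'
#' Sums the equivalent annual cost of every asset, applies the programme
#' allocation weight, scales to the analysis horizon, and divides by the
#' number of programme patients over that horizon.
#'
#' @param assets List of [capital_asset()]s.
#' @param weight Programme allocation fraction in `[0, 1]`.
#' @param n_patients Programme patients over the horizon (> 0).
#' @param rate Annual discount rate.
#' @param horizon_years Analysis horizon in years (default 96 weeks).
#' @return Currency per patient.
#' @export
capital_share_per_patient <- function(assets, weight, n_patients, rate = 0.03,
                                      horizon_years = 96 * 7 / 365.25) {
  assert_scalar_number(weight, "weight", min = 0, max = 1)
  assert_scalar_number(n_patients, "n_patients", min = 1)
  annual <- sum(purrr::map_dbl(assets, equivalent_annual_cost, rate = rate))
  annual * weight * horizon_years / n_patients
}
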