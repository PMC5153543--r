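# Per-patient cost engine.
#
# Total cost per treatment regimen is the micro-costing sum
#
#     total = labour (physician + nurse) + capital share + medications
#             + laboratory diagnostics
#
# with hospital care costed by the inpatient algorithm: inpatient cost =
# direct cost (medications dispensed during the stay) + overhead cost
# (length of stay times a per-bed-day rate that bundles catering,
# administration, security, building and transport shares). Drugs dispensed
# during an admission are counted once, inside the inpatient direct cost,
# never again under the outpatient medication component.

#' Cadre wage schedule
#'
#' Labour is costed from the monthly wage: the wage divided by monthly
#' contracted hours gives an hourly rate, multiplied by the per-visit contact
#' time and the number of visits.
#'
#' @param physician,nurse Lists with elements `monthly_wage` (currency),
#'   `monthly_hours` (> 0) and `visit_duration` (hours per visit, used when a
#'   visit has no recorded duration).
#' @return A `wage_schedule` list keyed by cadre.
#' @export
wage_schedule <- function(physician = list(monthly_wage = 1600, monthly_hours = 160,
                                           visit_duration = 0.5),
                          nurse = list(monthly_wage = 640, monthly_hours = 160,
                                       visit_duration = 0.5)) {
  sched <- list(physician = physician, nurse = nurse)
  for (cadre in names(sched)) {
    s <- sched[[cadre]]
    assert_scalar_number(s$monthly_wage, paste0(cadre, "$monthly_wage"), min = 0)
    assert_scalar_number(s$monthly_hours, paste0(cadre, "$monthly_hours"),
                         min = .Machine$double.xmin)
    assert_scalar_number(s$visit_duration, paste0(cadre, "$visit_duration"), min = 0)
  }
  structure(sched, class = "wage_schedule")
}

#' Labour cost of a patient's visits for one cadre
#'
#' Each visit of the cadre costs `(monthly_wage / monthly_hours) * duration`,
#' using the visit's recorded duration (falling back to the schedule's
#' per-visit default), summed over visits.
#'
#' @param visits Data frame with columns `cadre` and optionally `duration`.
#' @param schedule A [wage_schedule()].
#' @param cadre `"physician"` or `"nurse"`.
#' @return Currency (0 for no visits of the cadre).
#' @export
labour_cost <- function(visits, schedule, cadre) {
  s <- schedule[[norm_name(cadre)]]
  if (is.null(s)) abort(paste0("unknown cadre: ", cadre))
  v <- visits[norm_name(visits$cadre) == norm_name(cadre), , drop = FALSE]
  if (nrow(v) == 0) return(0)
  dur <- if ("duration" %in% names(v)) v$duration else rep(s$visit_duration, nrow(v))
  dur[is.na(dur)] <- s$visit_duration
  sum((s$monthly_wage / s$monthly_hours) * dur)
}

#' Assemble a costing context
#'
#' Bundles every price the engine needs: the drug price table, the wage
#' schedule, the per-bed-day inpatient overhead rate, the per-patient
#' annuitised capital share, a per-patient apportioned outpatient fixed-cost
#' share, and the laboratory pricing rule.
#'
#' Laboratory pricing has two modes. `"flat"` charges each patient one fixed
#' panel rate for the routine monitoring bloods (the trial protocol costed
#' the standard panel at a flat rate per patient, so the cohort SD of the
#' laboratory component is zero). `"per_test"` prices each recorded test from
#' `lab_price_table`.
#'
#' @param price_table `unit_cost_table` pricing every dispensable drug.
#' @param wages A [wage_schedule()].
#' @param per_day_rate Inpatient overhead per bed-day (currency).
#' @param capital_share Annuitised capital cost per patient (currency).
#' @param outpatient_fixed_share Apportioned outpatient fixed cost per
#'   patient (currency).
#' @param lab_pricing List: `mode = "flat"` with `flat_rate`, or
#'   `mode = "per_test"` with `lab_price_table` a `unit_cost_table`.
#' @return A `costing_context`.
#' @export
costing_context <- function(price_table,
                            wages = wage_schedule(),
                            per_day_rate = 0,
                            capital_share = 0,
                            outpatient_fixed_share = 0,
                            lab_pricing = list(mode = "flat", flat_rate = 15)) {
  assert_scalar_number(per_day_rate, "per_day_rate", min = 0)
  assert_scalar_number(capital_share, "capital_share", min = 0)
  assert_scalar_number(outpatient_fixed_share, "outpatient_fixed_share", min = 0)
  if (!lab_pricing$mode %in% c("flat", "per_test")) {
    abort("lab_pricing$mode must be \"flat\" or \"per_test\"")
  }
  if (lab_pricing$mode == "flat") {
    assert_scalar_number(lab_pricing$flat_rate, "lab_pricing$flat_rate", min = 0)
  } else if (is.null(lab_pricing$lab_price_table)) {
    abort("lab_pricing mode \"per_test\" requires `lab_price_table`")
  }
  structure(list(price_table = price_table, wages = wages,
                 per_day_rate = per_day_rate, capital_share = capital_share,
                 outpatient_fixed_share = outpatient_fixed_share,
                 lab_pricing = lab_pricing),
            class = "costing_context")
}

#' Cost of one hospital admission
#'
#' Direct cost (medications dispensed during the stay, valued by
#' [course_cost()]) plus overhead cost (length of stay times the context's
#' per-bed-day rate).
#'
#' @param hospitalisation List or one-row data frame with `length_of_stay`
#'   and a `dispenses` data frame (columns `drug_name`, `doses`).
#' @param ctx A [costing_context()].
#' @return Currency.
#' @export
inpatient_cost <- function(hospitalisation, ctx) {
  los <- hospitalisation$length_of_stay
  direct <- course_cost(hospitalisation$dispenses, ctx$price_table)
  direct + los * ctx$per_day_rate
}

#' Outpatient cost of a patient's ambulatory care
#'
#' Labour for outpatient visits of both cadres, plus outpatient medication,
#' plus laboratory diagnostics, plus the per-patient apportioned fixed-cost
#' share.
#'
#' @param visits,dispenses,labs Event data frames (outpatient events only).
#' @param ctx A [costing_context()].
#' @return Currency.
#' @export
outpatient_cost <- function(visits, dispenses, labs, ctx) {
  labour_cost(visits, ctx$wages, "physician") +
    labour_cost(visits, ctx$wages, "nurse") +
    course_cost(dispenses, ctx$price_table) +
    laboratory_component(labs, ctx, n_patients = 1) +
    ctx$outpatient_fixed_share
}

laboratory_component <- function(labs, ctx, n_patients = 1) {
  if (ctx$lab_pricing$mode == "flat") {
    ctx$lab_pricing$flat_rate * n_patients
  } else {
    lab_panel_cost(labs, ctx$lab_pricing$lab_price_table)
  }
}

#' Per-patient cost breakdown
#'
#' Computes every cost component for one censored patient record and the
#' micro-costing total. Components:
#' \describe{
#'   \item{physician, nursing}{outpatient labour per cadre.}
#'   \item{medication}{outpatient dispenses only.}
#'   \item{laboratory}{flat panel rate or per-test pricing.}
#'   \item{inpatient}{all admissions, direct drugs + bed-day overhead.}
#'   \item{outpatient}{roll-up: physician + nursing + medication +
#'     laboratory + outpatient fixed share. Reported for table layout; its
#'     parts are already counted, so it is excluded from `total`.}
#'   \item{capital_share}{annuitised capital per patient.}
#'   \item{total}{physician + nursing + medication + laboratory + inpatient
#'     + outpatient fixed share + capital share.}
#' }
#'
#' @param record A [patient_record()]; if `death_day` is set the record must
#'   already be censored (see [apply_death_censoring()]).
#' @param ctx A [costing_context()].
#' @return One-row tibble (`cost_breakdown`) with the components above.
#' @export
patient_total_cost <- function(record, ctx) {
  stopifnot(inherits(record, "patient_record"), inherits(ctx, "costing_context"))

  out <- withCallingHandlers(
    patient_total_cost_impl(record, ctx),
    error = function(e) {
      abort(paste0("costing failed for patient ", record$patient_id, ": ",
                   conditionMessage(e)), class = "microcost_costing_error")
    }
  )
  out
}

patient_total_cost_impl <- function(record, ctx) {
  outv <- record$visits[record$visits$setting == "outpatient", , drop = FALSE]
  physician <- labour_cost(outv, ctx$wages, "physician")
  nursing <- labour_cost(outv, ctx$wages, "nurse")

  # Outpatient dispenses are those not tied to an admission.
  outd <- record$dispenses[is.na(record$dispenses$hosp_id), , drop = FALSE]
  medication <- course_cost(outd, ctx$price_table)

  laboratory <- laboratory_component(record$lab_tests, ctx, n_patients = 1)

  hosp <- record$hospitalisations
  inpatient <- 0
  if (nrow(hosp) > 0) {
    for (k in seq_len(nrow(hosp))) {
      stay_disp <- record$dispenses[
        !is.na(record$dispenses$hosp_id) &
          record$dispenses$hosp_id == hosp$hosp_id[k], , drop = FALSE]
      inpatient <- inpatient + inpatient_cost(
        list(length_of_stay = hosp$length_of_stay[k], dispenses = stay_disp), ctx)
    }
  }

  outpatient <- physician + nursing + medication + laboratory +
    ctx$outpatient_fixed_share
  total <- physician + nursing + medication + laboratory + inpatient +
    ctx$outpatient_fixed_share + ctx$capital_share

  tibble::tibble(
    patient_id = record$patient_id,
    arm_label = record$arm_label,
    physician = physician, nursing = nursing, medication = medication,
    laboratory = laboratory, inpatient = inpatient, outpatient = outpatient,
    capital_share = ctx$capital_share, total = total
  )
}

#' Cost a whole cohort
#'
#' Applies [patient_total_cost()] to every patient in the cohort.
#'
#' @param cohort A `crf_cohort`.
#' @param ctx A [costing_context()].
#' @return Tibble with one `cost_breakdown` row per patient.
#' @export
cost_cohort <- function(cohort, ctx) {
  purrr::map_dfr(cohort_records(cohort), patient_total_cost, ctx = ctx)
}

#' Mean-impute component costs censored by death
#'
#' Resource use not captured because a patient died is treated as missing
#' and averaged out: each flagged component value is replaced by the arm
#' mean of the non-flagged values of that component. Non-flagged values are
#' untouched and the `total` column is recomputed for imputed rows.
#'
#' @param breakdowns Cohort breakdown tibble from [cost_cohort()].
#' @param missing_flags Data frame with columns `patient_id` and `component`
#'   naming the values to impute.
#' @return The breakdown tibble with flagged values imputed.
#' @export
impute_missing_visit_costs <- function(breakdowns, missing_flags) {
  if (is.null(missing_flags) || nrow(missing_flags) == 0) return(breakdowns)
  overlap_cols <- c("outpatient", "total")  # roll-ups, recomputed below
  fixed_shares <- breakdowns$total -
    (breakdowns$physician + breakdowns$nursing + breakdowns$medication +
       breakdowns$laboratory + breakdowns$inpatient + breakdowns$capital_share)
  for (component in unique(missing_flags$component)) {
    if (!component %in% setdiff(names(breakdowns),
                                c("patient_id", "arm_label", overlap_cols))) {
      abort(paste0("unknown cost component: ", component))
    }
    pids <- missing_flags$patient_id[missing_flags$component == component]
    flagged <- breakdowns$patient_id %in% pids
    for (arm in unique(breakdowns$arm_label[flagged])) {
      in_arm <- breakdowns$arm_label == arm
      donor <- in_arm & !flagged
      if (!any(donor)) {
        abort(paste0("cannot impute `", component, "` in arm ", arm,
                     ": every value is flagged missing"))
      }
      breakdowns[[component]][in_arm & flagged] <-
        mean(breakdowns[[component]][donor])
    }
  }
  breakdowns$outpatient <- breakdowns$physician + breakdowns$nursing +
    breakdowns$medication + breakdowns$laboratory + fixed_shares
  breakdowns$total <- breakdowns$physician + breakdowns$nursing +
    breakdowns$medication + breakdowns$laboratory + breakdowns$inpatient +
    breakdowns$capital_share + fixed_shares
  breakdowns
}
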