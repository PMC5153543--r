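# Synthetic case-report-form (CRF) generator.
#
# Real per-patient trial records are unavailable, so every downstream costing
# stage is exercised on seedable synthetic cohorts whose event streams carry
# the statistical structure a provider-perspective costing analysis assumes:
# Poisson visit and admission processes, heavy-tailed lengths of stay with an
# arm-specific hard cap, opportunistic-infection causes drawn at configured
# relative frequencies, and censoring of all events at death.

#' Configure one synthetic trial arm
#'
#' An `arm_config` fixes every stochastic ingredient of a synthetic cohort:
#' cohort size, follow-up horizon, cumulative mortality, per-patient Poisson
#' means for physician visits, nurse visits and hospital admissions, the
#' length-of-stay distribution with its hard cap, the opportunistic-infection
#' frequency table used to label admission causes, and the drug-dispensing
#' model. All randomness downstream flows from `seed`.
#'
#' @param arm_label `"cotrimoxazole"` or `"arv"`.
#' @param n_patients Number of children enrolled in the arm.
#' @param followup_days Follow-up horizon in days; enrolment is day 0 and all
#'   event days lie in the closed interval `[0, followup_days]`.
#' @param mortality_prob Probability that a patient dies during follow-up
#'   (cumulative mortality). Death day is uniform over the follow-up window
#'   and all later events are censored.
#' @param physician_visit_rate,nursing_visit_rate Mean outpatient visits per
#'   patient over the whole follow-up (Poisson means).
#' @param hosp_episode_rate Mean hospital admissions per patient (Poisson mean).
#' @param los_distribution Length-of-stay model: a list with `meanlog`,
#'   `sdlog` (log-normal parameters, days) and `cap` (hard maximum stay in
#'   days). Sampled stays are rounded up to whole days and truncated to
#'   `[1, cap]`.
#' @param oi_frequency_table Opportunistic-infection condition table: a data
#'   frame with columns `condition` and `frequency` (relative frequencies;
#'   normalised internally). Defaults to the bundled paediatric HIV staging
#'   condition table, see [oi_condition_table()].
#' @param dispense_model Drug-dispensing model: a list with `primary_drug`
#'   (the arm's study medication), `primary_doses_per_day` (outpatient doses
#'   per day alive), and `inpatient_drugs`, a data frame with columns
#'   `drug_name` and `mean_doses` giving the Poisson mean number of doses of
#'   each drug dispensed during one admission.
#' @param visit_duration_hours Named list of per-visit contact time in hours
#'   by cadre (`physician`, `nurse`).
#' @param lab_panel Character vector of test names drawn at each nurse visit.
#' @param seed Master integer seed for the arm.
#'
#' @return An object of class `arm_config` (a validated list).
#' @seealso [generate_cohort()], [chap_arm_config()], [chapas_arm_config()]
#' @export
#' @examples
#' cfg <- arm_config("arv", n_patients = 20, followup_days = 336,
#'                   physician_visit_rate = 14.2, seed = 1)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$patients)
arm_config <- function(arm_label,
                       n_patients,
                       followup_days,
                       mortality_prob = 0,
                       physician_visit_rate = 0,
                       nursing_visit_rate = 0,
                       hosp_episode_rate = 0,
                       los_distribution = list(meanlog = 1.6, sdlog = 0.9, cap = 37),
                       oi_frequency_table = NULL,
                       dispense_model = NULL,
                       visit_duration_hours = list(physician = 0.5, nurse = 0.5),
                       lab_panel = c("haematology", "biochemistry",
                                     "lymphocyte subsets", "microbiology"),
                       seed = 1L) {
  if (!is.character(arm_label) || length(arm_label) != 1 ||
      !arm_label %in% c("cotrimoxazole", "arv")) {
    stop_field("arm_label", "must be \"cotrimoxazole\" or \"arv\"")
  }
  assert_scalar_number(n_patients, "n_patients", min = 1, integerish = TRUE)
  assert_scalar_number(followup_days, "followup_days", min = 1, integerish = TRUE)
  assert_scalar_number(mortality_prob, "mortality_prob", min = 0, max = 1)
  assert_scalar_number(physician_visit_rate, "physician_visit_rate", min = 0)
  assert_scalar_number(nursing_visit_rate, "nursing_visit_rate", min = 0)
  assert_scalar_number(hosp_episode_rate, "hosp_episode_rate", min = 0)
  assert_scalar_number(seed, "seed", integerish = TRUE)

  if (!is.list(los_distribution)) stop_field("los_distribution", "must be a list")
  for (f in c("meanlog", "sdlog", "cap")) {
    if (is.null(los_distribution[[f]])) {
      stop_field("los_distribution", paste0("missing element `", f, "`"))
    }
  }
  assert_scalar_number(los_distribution$sdlog, "los_distribution$sdlog", min = 0)
  assert_scalar_number(los_distribution$cap, "los_distribution$cap", min = 1,
                       integerish = TRUE)

  oi_frequency_table <- oi_frequency_table %||% oi_condition_table()
  oi_frequency_table <- validate_oi_table(oi_frequency_table)

  dispense_model <- dispense_model %||% default_dispense_model(arm_label)
  if (!is.list(dispense_model) ||
      is.null(dispense_model$primary_drug) ||
      is.null(dispense_model$primary_doses_per_day)) {
    stop_field("dispense_model",
               "must be a list with `primary_drug` and `primary_doses_per_day`")
  }
  assert_scalar_number(dispense_model$primary_doses_per_day,
                       "dispense_model$primary_doses_per_day", min = 0)
  if (!is.null(dispense_model$inpatient_drugs)) {
    ip <- dispense_model$inpatient_drugs
    if (!is.data.frame(ip) || !all(c("drug_name", "mean_doses") %in% names(ip))) {
      stop_field("dispense_model$inpatient_drugs",
                 "must have columns drug_name and mean_doses")
    }
    if (any(ip$mean_doses < 0)) {
      stop_field("dispense_model$inpatient_drugs", "mean_doses must be >= 0")
    }
  }

  structure(
    list(
      arm_label = arm_label,
      n_patients = as.integer(n_patients),
      followup_days = as.integer(followup_days),
      mortality_prob = mortality_prob,
      physician_visit_rate = physician_visit_rate,
      nursing_visit_rate = nursing_visit_rate,
      hosp_episode_rate = hosp_episode_rate,
      los_distribution = los_distribution,
      oi_frequency_table = oi_frequency_table,
      dispense_model = dispense_model,
      visit_duration_hours = visit_duration_hours,
      lab_panel = lab_panel,
      seed = as.integer(seed)
    ),
    class = "arm_config"
  )
}

validate_oi_table <- function(tab) {
  if (!is.data.frame(tab) || !all(c("condition", "frequency") %in% names(tab))) {
    stop_field("oi_frequency_table",
               "must be a data frame with columns condition and frequency")
  }
  if (nrow(tab) == 0) stop_field("oi_frequency_table", "must be nonempty")
  if (any(tab$frequency < 0)) stop_field("oi_frequency_table", "frequencies must be >= 0")
  if (sum(tab$frequency) <= 0) {
    stop_field("oi_frequency_table", "frequencies must not all be zero")
  }
  tibble::as_tibble(tab[, c("condition", "frequency")])
}

default_dispense_model <- function(arm_label) {
  inpatient <- tibble::tibble(
    drug_name = c("Ceftriaxone", "Amoxycillin", "Coartem", "Cotrimoxazole"),
    mean_doses = c(4, 15, 6, 10)
  )
  if (arm_label == "arv") {
    list(primary_drug = "Pedimune Baby", primary_doses_per_day = 2,
         inpatient_drugs = inpatient)
  } else {
    list(primary_drug = "Cotrimoxazole", primary_doses_per_day = 1,
         inpatient_drugs = inpatient)
  }
}

#' Preset arm configurations for the two paediatric trials
#'
#' `chap_arm_config()` encodes the cotrimoxazole-prophylaxis trial arm:
#' 265 children, two-year (672-day) follow-up, cumulative mortality 186/534
#' (the pooled deaths over both randomised groups, 265 + 269 = 534), and a
#' 77-day cap on any single hospital stay. `chapas_arm_config()` encodes the
#' antiretroviral (fixed-dose combination) trial arm: 211 children, 48-week
#' (336-day) follow-up, 22/211 cumulative mortality, and a 37-day stay cap.
#' Every field can be overridden through `...`.
#'
#' @param ... Overrides passed to [arm_config()].
#' @return An [arm_config()] object.
#' @export
chap_arm_config <- function(...) {
  defaults <- list(
    arm_label = "cotrimoxazole",
    n_patients = 265,
    followup_days = 672,
    mortality_prob = 186 / 534,
    physician_visit_rate = 11,
    nursing_visit_rate = 0.65,
    hosp_episode_rate = 1.2,
    los_distribution = list(meanlog = 1.6, sdlog = 0.9, cap = 77),
    seed = 20061L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(arm_config, args)
}

#' @rdname chap_arm_config
#' @export
chapas_arm_config <- function(...) {
  defaults <- list(
    arm_label = "arv",
    n_patients = 211,
    followup_days = 336,
    mortality_prob = 22 / 211,
    physician_visit_rate = 14.2,
    nursing_visit_rate = 8,
    hosp_episode_rate = 0.15,
    los_distribution = list(meanlog = 1.2, sdlog = 0.8, cap = 37),
    seed = 20062L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(arm_config, args)
}

#' Sample integer lengths of stay
#'
#' Stays are log-normal on the day scale, rounded up to whole days, then
#' truncated to `[1, cap]`, reproducing the right-skewed stay distributions
#' seen in paediatric HIV admissions while honouring the arm's recorded
#' maximum stay.
#'
#' @param n Number of stays to sample.
#' @param los_distribution As in [arm_config()].
#' @return Integer vector of stays in days, each in `[1, cap]`.
#' @export
sample_length_of_stay <- function(n, los_distribution) {
  raw <- ceiling(rlnorm(n, los_distribution$meanlog, los_distribution$sdlog))
  as.integer(pmin(pmax(raw, 1), los_distribution$cap))
}

#' Sample opportunistic-infection conditions
#'
#' Draws condition labels with probability proportional to the table's
#' relative frequencies.
#'
#' @param n Number of draws.
#' @param oi_table Data frame with columns `condition` and `frequency`.
#' @return Character vector of length `n`.
#' @export
sample_oi_conditions <- function(n, oi_table) {
  oi_table <- validate_oi_table(oi_table)
  if (n == 0) return(character())
  p <- oi_table$frequency / sum(oi_table$frequency)
  as.character(sample(oi_table$condition, n, replace = TRUE, prob = p))
}

#' Assign opportunistic-infection causes to a patient's admissions
#'
#' Re-draws the `cause` label of every hospitalisation in the record from the
#' given condition table; over many draws the empirical cause frequencies
#' converge to the table's relative frequencies.
#'
#' @param record A [patient_record()].
#' @param oi_table Data frame with columns `condition` and `frequency`.
#' @param seed Optional integer seed for reproducible assignment.
#' @return The record with hospitalisation causes re-assigned.
#' @export
sample_oi_events <- function(record, oi_table, seed = NULL) {
  stopifnot(inherits(record, "patient_record"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(record$hospitalisations)
  if (n > 0) {
    record$hospitalisations$cause <- sample_oi_conditions(n, oi_table)
  }
  record
}

# One patient's event stream, drawn from the patient's own substream seed.
# Returns plain vectors (no tibbles) so large cohorts assemble quickly; the
# cohort-level tables are built once in generate_cohort().
generate_patient_raw <- function(config, i) {
  set.seed(patient_substream_seed(config$seed, i))
  fup <- config$followup_days
  pid <- sprintf("%s-%04d", toupper(substr(config$arm_label, 1, 3)), i)

  dies <- runif(1) < config$mortality_prob
  death_day <- if (dies) sample.int(fup + 1L, 1L) - 1L else NA_integer_

  n_phys <- rpois(1, config$physician_visit_rate)
  n_nurse <- rpois(1, config$nursing_visit_rate)
  visit_day <- c(sample.int(fup + 1L, n_phys, replace = TRUE) - 1L,
                 sample.int(fup + 1L, n_nurse, replace = TRUE) - 1L)
  visit_cadre <- rep(c("physician", "nurse"), c(n_phys, n_nurse))
  visit_duration <- c(rep(config$visit_duration_hours$physician, n_phys),
                      rep(config$visit_duration_hours$nurse, n_nurse))

  n_hosp <- rpois(1, config$hosp_episode_rate)
  hosp_id <- if (n_hosp > 0) sprintf("%s-H%02d", pid, seq_len(n_hosp)) else character()
  hosp_start <- sample.int(fup + 1L, n_hosp, replace = TRUE) - 1L
  hosp_los <- sample_length_of_stay(n_hosp, config$los_distribution)
  hosp_cause <- sample_oi_conditions(n_hosp, config$oi_frequency_table)

  # Inpatient dispenses: for each admission, each drug in the inpatient model
  # is dispensed a Poisson number of doses on the admission day.
  dm <- config$dispense_model
  ip <- dm$inpatient_drugs
  if (n_hosp > 0 && !is.null(ip) && nrow(ip) > 0) {
    d_hosp_id <- rep(hosp_id, each = nrow(ip))
    d_drug <- rep(ip$drug_name, times = n_hosp)
    d_doses <- rpois(n_hosp * nrow(ip), rep(ip$mean_doses, times = n_hosp))
    d_day <- rep(hosp_start, each = nrow(ip))
    keep <- d_doses > 0
    d_hosp_id <- d_hosp_id[keep]; d_drug <- d_drug[keep]
    d_doses <- d_doses[keep]; d_day <- d_day[keep]
  } else {
    d_hosp_id <- character(); d_drug <- character()
    d_doses <- integer(); d_day <- integer()
  }

  # Outpatient study-medication dispenses: accrued per day alive on study,
  # recorded as one dispense event at enrolment (day 0).
  days_on_study <- if (dies) death_day + 1L else fup + 1L
  primary_doses <- as.integer(round(dm$primary_doses_per_day * days_on_study))
  if (primary_doses > 0) {
    d_hosp_id <- c(NA_character_, d_hosp_id)
    d_drug <- c(dm$primary_drug, d_drug)
    d_doses <- c(primary_doses, d_doses)
    d_day <- c(0L, d_day)
  }

  # Laboratory panel drawn at each nurse visit (routine monitoring bloods).
  nurse_days <- visit_day[visit_cadre == "nurse"]
  n_panel <- length(config$lab_panel)
  lab_name <- rep(config$lab_panel, times = length(nurse_days))
  lab_day <- rep(nurse_days, each = n_panel)

  list(pid = pid, death_day = death_day,
       visit_day = visit_day, visit_cadre = visit_cadre,
       visit_duration = visit_duration,
       hosp_id = hosp_id, hosp_start = hosp_start, hosp_los = hosp_los,
       hosp_cause = hosp_cause,
       d_hosp_id = d_hosp_id, d_drug = d_drug, d_doses = d_doses, d_day = d_day,
       lab_name = lab_name, lab_day = lab_day)
}

# Vectorised cohort-level death censoring with the same semantics as
# apply_death_censoring(): drop events after death, shorten straddling stays.
censor_cohort <- function(cohort) {
  pat <- cohort$patients
  dd <- setNames(ifelse(is.na(pat$death_day), Inf, pat$death_day), pat$patient_id)

  cohort$visits <- cohort$visits[cohort$visits$day <= dd[cohort$visits$patient_id], ]
  cohort$lab_tests <-
    cohort$lab_tests[cohort$lab_tests$day <= dd[cohort$lab_tests$patient_id], ]

  hosp <- cohort$hospitalisations
  hosp_dd <- dd[hosp$patient_id]
  hosp <- hosp[hosp$start_day <= hosp_dd, ]
  hosp_dd <- dd[hosp$patient_id]
  hosp$length_of_stay <- as.integer(pmin(hosp$length_of_stay,
                                         hosp_dd - hosp$start_day + 1))
  cohort$hospitalisations <- hosp

  disp <- cohort$dispenses
  disp <- disp[disp$day <= dd[disp$patient_id], ]
  disp <- disp[is.na(disp$hosp_id) | disp$hosp_id %in% hosp$hosp_id, ]
  cohort$dispenses <- disp
  cohort
}

empty_dispenses <- function() {
  tibble::tibble(patient_id = character(), hosp_id = character(),
                 drug_name = character(), doses = integer(), day = integer())
}

#' Generate a synthetic trial cohort
#'
#' Draws `n_patients` independent case-report-form event streams from the arm
#' configuration. Each patient has a deterministic substream seed derived
#' from the master seed and the patient index, so the same configuration and
#' seed always reproduce the identical cohort, and growing the cohort never
#' reshuffles earlier patients.
#'
#' @param config An [arm_config()].
#' @return A `crf_cohort`: a list of tibbles `patients`, `visits`,
#'   `hospitalisations`, `dispenses`, `lab_tests`, with the generating
#'   configuration attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "arm_config"))
  raws <- purrr::map(seq_len(config$n_patients),
                     function(i) generate_patient_raw(config, i))

  pids <- purrr::map_chr(raws, "pid")
  pull <- function(field) unlist(purrr::map(raws, field), use.names = FALSE)
  rep_pid <- function(field) {
    rep(pids, purrr::map_int(raws, function(r) length(r[[field]])))
  }

  cohort <- structure(
    list(
      patients = tibble::tibble(
        patient_id = pids, arm_label = config$arm_label, enrolment_day = 0L,
        followup_days = config$followup_days,
        death_day = as.integer(pull("death_day"))),
      visits = tibble::tibble(
        patient_id = rep_pid("visit_day"), day = as.integer(pull("visit_day")),
        cadre = as.character(pull("visit_cadre")),
        duration = as.numeric(pull("visit_duration")), setting = "outpatient"),
      hospitalisations = tibble::tibble(
        patient_id = rep_pid("hosp_id"), hosp_id = as.character(pull("hosp_id")),
        start_day = as.integer(pull("hosp_start")),
        length_of_stay = as.integer(pull("hosp_los")),
        cause = as.character(pull("hosp_cause"))),
      dispenses = tibble::tibble(
        patient_id = rep_pid("d_drug"), hosp_id = as.character(pull("d_hosp_id")),
        drug_name = as.character(pull("d_drug")),
        doses = as.integer(pull("d_doses")), day = as.integer(pull("d_day"))),
      lab_tests = tibble::tibble(
        patient_id = rep_pid("lab_name"), test_name = as.character(pull("lab_name")),
        day = as.integer(pull("lab_day")))
    ),
    class = "crf_cohort"
  )
  cohort <- censor_cohort(cohort)
  attr(cohort, "config") <- config
  cohort
}

#' Construct a single patient record
#'
#' The unit of costing: one child's full case-report-form event stream.
#'
#' @param patient_id Opaque identifier.
#' @param arm_label Trial arm label.
#' @param followup_days Follow-up horizon in days.
#' @param death_day Integer day of death, or `NA` if the patient survives.
#' @param visits,hospitalisations,dispenses,lab_tests Event tibbles as
#'   produced by [generate_cohort()]; defaults are empty.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, arm_label = "arv", followup_days = 336L,
                           death_day = NA_integer_,
                           visits = NULL, hospitalisations = NULL,
                           dispenses = NULL, lab_tests = NULL) {
  structure(
    list(
      patient_id = patient_id,
      arm_label = arm_label,
      followup_days = as.integer(followup_days),
      death_day = if (is.na(death_day)) NA_integer_ else as.integer(death_day),
      visits = visits %||% tibble::tibble(
        patient_id = character(), day = integer(), cadre = character(),
        duration = numeric(), setting = character()),
      hospitalisations = hospitalisations %||% tibble::tibble(
        patient_id = character(), hosp_id = character(), start_day = integer(),
        length_of_stay = integer(), cause = character()),
      dispenses = dispenses %||% empty_dispenses(),
      lab_tests = lab_tests %||% tibble::tibble(
        patient_id = character(), test_name = character(), day = integer())
    ),
    class = "patient_record"
  )
}

#' Censor a patient record at death
#'
#' Resource use stops at the death event: every visit, admission, dispense
#' and test after `death_day` is dropped, events on or before it are kept
#' unchanged, and admissions straddling the death day are shortened so the
#' stay ends on it.
#'
#' @param record A [patient_record()].
#' @param death_day Non-negative integer day of death.
#' @return The censored record with `death_day` set.
#' @export
apply_death_censoring <- function(record, death_day) {
  stopifnot(inherits(record, "patient_record"))
  assert_scalar_number(death_day, "death_day", min = 0, integerish = TRUE)
  death_day <- as.integer(death_day)

  record$visits <- record$visits[record$visits$day <= death_day, ]
  record$lab_tests <- record$lab_tests[record$lab_tests$day <= death_day, ]

  hosp <- record$hospitalisations[record$hospitalisations$start_day <= death_day, ]
  if (nrow(hosp) > 0) {
    end_day <- hosp$start_day + hosp$length_of_stay - 1L
    hosp$length_of_stay <- as.integer(
      ifelse(end_day > death_day, death_day - hosp$start_day + 1L, hosp$length_of_stay))
  }
  record$hospitalisations <- hosp
  disp <- record$dispenses[record$dispenses$day <= death_day, ]
  record$dispenses <- disp[is.na(disp$hosp_id) | disp$hosp_id %in% hosp$hosp_id, ]
  record$death_day <- death_day
  record
}

#' Split a cohort into per-patient records
#'
#' @param cohort A `crf_cohort` from [generate_cohort()] or [read_cohort()].
#' @return Named list of [patient_record()] objects, in cohort order.
#' @export
cohort_records <- function(cohort) {
  stopifnot(inherits(cohort, "crf_cohort"))
  recs <- purrr::pmap(cohort$patients, function(patient_id, arm_label,
                                                enrolment_day, followup_days,
                                                death_day) {
    pid <- patient_id
    patient_record(
      patient_id = pid, arm_label = arm_label, followup_days = followup_days,
      death_day = death_day,
      visits = cohort$visits[cohort$visits$patient_id == pid, ],
      hospitalisations =
        cohort$hospitalisations[cohort$hospitalisations$patient_id == pid, ],
      dispenses = cohort$dispenses[cohort$dispenses$patient_id == pid, ],
      lab_tests = cohort$lab_tests[cohort$lab_tests$patient_id == pid, ]
    )
  })
  setNames(recs, cohort$patients$patient_id)
}

#' Write / read a cohort as plain CSV tables
#'
#' `write_cohort()` writes one CSV per event table (`patients.csv`,
#' `visits.csv`, `hospitalisations.csv`, `dispenses.csv`, `lab_tests.csv`)
#' plus a `manifest.json` recording the generating configuration and seed.
#' `read_cohort()` reads them back.
#'
#' @param cohort A `crf_cohort`.
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `crf_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "crf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort)) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  config <- attr(cohort, "config")
  if (!is.null(config)) {
    manifest <- config
    class(manifest) <- NULL
    manifest$oi_frequency_table <- NULL   # tabular; regenerate from source CSV
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  read1 <- function(nm, types) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")), col_types = types,
                    na = "", progress = FALSE)
  }
  structure(
    list(
      patients = read1("patients", "cciii"),
      visits = read1("visits", "cicdc"),
      hospitalisations = read1("hospitalisations", "cciic"),
      dispenses = read1("dispenses", "cccii"),
      lab_tests = read1("lab_tests", "cci")
    ),
    class = "crf_cohort"
  )
}
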