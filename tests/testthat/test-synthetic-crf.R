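# Synthetic case-report-form generator.

test_that("invalid arm configurations are rejected with the field named", {
  cases <- list(
    list(args = list(physician_visit_rate = -1), field = "physician_visit_rate"),
    list(args = list(mortality_prob = 1.5), field = "mortality_prob"),
    list(args = list(n_patients = 0), field = "n_patients"),
    list(args = list(los_distribution = list(meanlog = 1, sdlog = 1, cap = 0)),
         field = "cap"),
    list(args = list(hosp_episode_rate = -0.1), field = "hosp_episode_rate")
  )
  for (case in cases) {
    args <- utils::modifyList(
      list(arm_label = "arv", n_patients = 5, followup_days = 30), case$args)
    expect_error(do.call(arm_config, args), case$field,
                 class = "microcost_validation_error")
  }
})

test_that("generated cohorts have the configured size and honour record invariants", {
  cfg <- arm_config("arv", n_patients = 211, followup_days = 336,
                    mortality_prob = 0.25, physician_visit_rate = 6,
                    nursing_visit_rate = 3, hosp_episode_rate = 1, seed = 11)
  co <- generate_cohort(cfg)
  expect_identical(nrow(co$patients), 211L)

  all_events <- dplyr::bind_rows(
    co$visits[c("patient_id", "day")],
    co$lab_tests[c("patient_id", "day")],
    co$dispenses[c("patient_id", "day")],
    dplyr::transmute(co$hospitalisations, patient_id, day = start_day))
  expect_true(all(all_events$day >= 0 & all_events$day <= 336))

  # censoring soundness: no event after the patient's death day
  dd <- setNames(ifelse(is.na(co$patients$death_day), Inf, co$patients$death_day),
                 co$patients$patient_id)
  expect_true(all(all_events$day <= dd[all_events$patient_id]))

  los <- co$hospitalisations$length_of_stay
  expect_true(all(los >= 1 & los <= cfg$los_distribution$cap))
})

test_that("the same configuration and seed reproduce a byte-identical cohort", {
  cfg <- chapas_arm_config(n_patients = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  expect_identical(unname(dir_checksums(d1)), unname(dir_checksums(d2)))
})

test_that("growing the cohort does not reshuffle earlier patients", {
  small <- generate_cohort(chap_arm_config(n_patients = 15))
  large <- generate_cohort(chap_arm_config(n_patients = 30))
  keep <- large$visits$patient_id %in% small$patients$patient_id
  expect_identical(small$visits, large$visits[keep, ])
})

test_that("death censoring truncates records at the death day", {
  rec <- patient_record(
    "P1", followup_days = 60,
    visits = tibble::tibble(patient_id = "P1", day = c(3L, 10L, 40L),
                            cadre = "physician", duration = 0.5,
                            setting = "outpatient"))
  out <- apply_death_censoring(rec, 10)
  expect_identical(out$visits$day, c(3L, 10L))
  expect_identical(out$death_day, 10L)

  # death after the last event: record unchanged apart from death_day
  out2 <- apply_death_censoring(rec, 59)
  expect_identical(out2$visits, rec$visits)
  expect_identical(out2$death_day, 59L)

  # boundary: death on enrolment day keeps only day-0 events
  rec0 <- patient_record(
    "P2", followup_days = 60,
    visits = tibble::tibble(patient_id = "P2", day = c(0L, 1L),
                            cadre = "nurse", duration = 0.5,
                            setting = "outpatient"))
  expect_identical(apply_death_censoring(rec0, 0)$visits$day, 0L)

  # an empty record passes through
  expect_identical(apply_death_censoring(patient_record("P3"), 5)$death_day, 5L)
})

test_that("censoring shortens admissions straddling the death day", {
  rec <- patient_record(
    "P1", followup_days = 60,
    hospitalisations = tibble::tibble(
      patient_id = "P1", hosp_id = c("H1", "H2"), start_day = c(5L, 30L),
      length_of_stay = c(10L, 10L), cause = "Pneumonia"),
    dispenses = tibble::tibble(
      patient_id = "P1", hosp_id = c("H1", "H2"), drug_name = "DrugA",
      doses = c(3L, 4L), day = c(5L, 30L)))
  out <- apply_death_censoring(rec, 8)
  expect_identical(out$hospitalisations$hosp_id, "H1")
  expect_identical(out$hospitalisations$length_of_stay, 4L)  # days 5..8
  expect_identical(out$dispenses$hosp_id, "H1")
})

test_that("cohort-level censoring agrees with censoring each record", {
  cfg <- arm_config("cotrimoxazole", n_patients = 25, followup_days = 120,
                    mortality_prob = 0.6, physician_visit_rate = 8,
                    nursing_visit_rate = 4, hosp_episode_rate = 2, seed = 13)
  co <- generate_cohort(cfg)
  for (rec in cohort_records(co)) {
    if (is.na(rec$death_day)) next
    # re-censoring an already censored record must be a no-op
    again <- apply_death_censoring(rec, rec$death_day)
    expect_identical(again$visits, rec$visits)
    expect_identical(again$hospitalisations, rec$hospitalisations)
    expect_identical(again$dispenses, rec$dispenses)
  }
})

test_that("length-of-stay samples respect the hard cap", {
  los <- sample_length_of_stay(10000, list(meanlog = 1.6, sdlog = 0.9, cap = 77))
  expect_true(all(los >= 1 & los <= 77))
  expect_gt(max(los), 20)  # the tail actually reaches high stays
})

test_that("opportunistic-infection sampling follows the table frequencies", {
  one <- tibble::tibble(condition = "Pneumonia", frequency = 5)
  expect_identical(unique(sample_oi_conditions(50, one)), "Pneumonia")

  mixed <- tibble::tibble(condition = c("A", "B", "C"), frequency = c(2, 0, 8))
  set.seed(1)
  draws <- sample_oi_conditions(2000, mixed)
  expect_false("B" %in% draws)

  expect_error(sample_oi_conditions(5, tibble::tibble(condition = character(),
                                                      frequency = numeric())),
               "nonempty")

  tab <- oi_condition_table()
  set.seed(42)
  draws <- sample_oi_conditions(100000, tab)
  p <- tab$frequency[grepl("persistent fever", tab$condition)] / sum(tab$frequency)
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(mean(grepl("persistent fever", draws)) - p), 3 * se)
})

test_that("sample_oi_events reassigns admission causes reproducibly", {
  rec <- random_small_record(5)
  if (nrow(rec$hospitalisations) == 0) {
    rec$hospitalisations <- tibble::tibble(
      patient_id = "P1", hosp_id = "P1-H01", start_day = 1L,
      length_of_stay = 3L, cause = "x")
  }
  tab <- tibble::tibble(condition = c("A", "B"), frequency = c(1, 3))
  r1 <- sample_oi_events(rec, tab, seed = 7)
  r2 <- sample_oi_events(rec, tab, seed = 7)
  expect_identical(r1$hospitalisations$cause, r2$hospitalisations$cause)
  expect_true(all(r1$hospitalisations$cause %in% c("A", "B")))
})

test_that("empirical visit rates and mortality recover the configuration", {
  cfg <- arm_config("arv", n_patients = 10000, followup_days = 336,
                    mortality_prob = 0.104, physician_visit_rate = 4.5,
                    seed = 17)
  co <- generate_cohort(cfg)

  death_frac <- mean(!is.na(co$patients$death_day))
  se_mort <- sqrt(0.104 * (1 - 0.104) / 10000)
  expect_lt(abs(death_frac - 0.104), 3 * se_mort)

  # visit counts are Poisson before censoring; check on survivors
  surv <- co$patients$patient_id[is.na(co$patients$death_day)]
  n_vis <- tabulate(factor(co$visits$patient_id[co$visits$cadre == "physician"],
                           levels = surv), nbins = length(surv))
  se_rate <- sqrt(4.5 / length(surv))
  expect_lt(abs(mean(n_vis) - 4.5), 3 * se_rate)
})

test_that("cohorts round-trip through CSV unchanged", {
  co <- generate_cohort(chapas_arm_config(n_patients = 12))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  for (nm in names(back)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(co[[nm]]),
                 ignore_attr = TRUE)
  }
})
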