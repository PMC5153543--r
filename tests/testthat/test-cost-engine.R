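# Per-patient cost engine.

test_that("labour cost is visits times the hourly wage share", {
  sched <- wage_schedule(
    physician = list(monthly_wage = 1200, monthly_hours = 160, visit_duration = 0.5))
  visits <- tibble::tibble(cadre = rep("physician", 4), duration = 0.5)
  expect_equal(labour_cost(visits, sched, "physician"), 4 * (1200 / 160) * 0.5)
  expect_equal(labour_cost(visits, sched, "physician"), 15)

  expect_identical(labour_cost(visits[0, ], sched, "physician"), 0)
  expect_equal(labour_cost(dplyr::bind_rows(visits, visits), sched, "physician"),
               2 * labour_cost(visits, sched, "physician"))
  expect_error(labour_cost(visits, sched, "pharmacist"), "pharmacist")
})

test_that("inpatient cost is direct drug cost plus bed-day overhead", {
  ctx <- toy_context(per_day_rate = 10)
  expect_identical(inpatient_cost(list(length_of_stay = 0, dispenses = NULL), ctx), 0)

  stay <- list(length_of_stay = 10,
               dispenses = tibble::tibble(drug_name = "DrugB", doses = c(4, 4),
                                          hosp_id = "H1"))
  expect_equal(inpatient_cost(stay, ctx), 10 * 10 + 8 * 2.25)

  direct <- course_cost(stay$dispenses, ctx$price_table)
  overhead <- stay$length_of_stay * ctx$per_day_rate
  expect_equal(inpatient_cost(stay, ctx), direct + overhead)
})

test_that("outpatient cost composes labour, drugs, labs and the fixed share", {
  ctx <- toy_context(outpatient_fixed_share = 0, flat_rate = 0)
  none <- outpatient_cost(tibble::tibble(cadre = character(), duration = numeric()),
                          NULL, character(), ctx)
  expect_identical(none, 0)

  ctx2 <- toy_context(outpatient_fixed_share = 0, flat_rate = 15)
  one <- outpatient_cost(
    tibble::tibble(cadre = "nurse", duration = 0.25), NULL, character(), ctx2)
  expect_equal(one, (480 / 160) * 0.25 + 15)
})

test_that("an empty record in a zero-share context costs nothing", {
  ctx <- toy_context(per_day_rate = 0, capital_share = 0,
                     outpatient_fixed_share = 0, flat_rate = 0)
  bd <- patient_total_cost(patient_record("P0"), ctx)
  expect_equal(bd$total, 0)
  expect_true(all(unlist(bd[c("physician", "nursing", "medication", "laboratory",
                              "inpatient", "outpatient", "capital_share")]) == 0))
})

test_that("a patient with only the standard panel costs the flat panel rate", {
  ctx <- toy_context(per_day_rate = 0, capital_share = 0,
                     outpatient_fixed_share = 0, flat_rate = 15)
  bd <- patient_total_cost(patient_record("P0"), ctx)
  expect_equal(bd$total, 15)
  expect_equal(bd$laboratory, 15)
})

test_that("the engine matches a brute-force event-loop oracle on random records", {
  ctx <- toy_context()
  for (seed in 1:30) {
    rec <- random_small_record(seed)
    bd <- patient_total_cost(rec, ctx)
    expect_equal(bd$total, brute_force_total(rec, ctx),
                 tolerance = 1e-12, label = paste("record seed", seed))
    # decomposition: the roll-ups are consistent with the components
    expect_equal(bd$total,
                 bd$physician + bd$nursing + bd$medication + bd$laboratory +
                   bd$inpatient + bd$capital_share +
                   ctx$outpatient_fixed_share,
                 tolerance = 1e-12)
    expect_equal(bd$outpatient,
                 bd$physician + bd$nursing + bd$medication + bd$laboratory +
                   ctx$outpatient_fixed_share,
                 tolerance = 1e-12)
  }
})

test_that("earlier death censoring never increases any cost component", {
  ctx <- toy_context()
  comps <- c("physician", "nursing", "medication", "laboratory", "inpatient",
             "outpatient", "total")
  for (seed in 1:12) {
    rec <- random_small_record(seed)
    days <- sort(unique(c(0L, 10L, 25L, 50L)), decreasing = TRUE)
    prev <- patient_total_cost(rec, ctx)
    for (d in days) {
      cur <- patient_total_cost(apply_death_censoring(rec, d), ctx)
      for (comp in comps) {
        expect_lte(cur[[comp]], prev[[comp]] + 1e-12)
      }
      prev <- cur
    }
  }
})

test_that("breakdowns scale linearly with all unit prices and wages", {
  c1 <- toy_context()
  scale <- 3.7
  tab <- toy_price_table()
  tab$unit_price <- tab$unit_price * scale
  c2 <- costing_context(
    unit_cost_table(tab),
    wages = wage_schedule(
      physician = list(monthly_wage = 1200 * scale, monthly_hours = 160,
                       visit_duration = 0.5),
      nurse = list(monthly_wage = 480 * scale, monthly_hours = 160,
                   visit_duration = 0.25)),
    per_day_rate = 10 * scale, capital_share = 2 * scale,
    outpatient_fixed_share = 1 * scale,
    lab_pricing = list(mode = "flat", flat_rate = 15 * scale))
  for (seed in 1:8) {
    rec <- random_small_record(seed)
    b1 <- patient_total_cost(rec, c1)
    b2 <- patient_total_cost(rec, c2)
    for (comp in c("physician", "nursing", "medication", "laboratory",
                   "inpatient", "outpatient", "capital_share", "total")) {
      expect_equal(b2[[comp]], scale * b1[[comp]], tolerance = 1e-12)
    }
  }
})

test_that("cohort costing conserves totals across patients and components", {
  cfg <- arm_config("arv", n_patients = 40, followup_days = 100,
                    mortality_prob = 0.2, physician_visit_rate = 5,
                    nursing_visit_rate = 2, hosp_episode_rate = 1, seed = 23,
                    dispense_model = list(
                      primary_drug = "DrugB", primary_doses_per_day = 1,
                      inpatient_drugs = tibble::tibble(drug_name = "DrugA",
                                                       mean_doses = 4)))
  ctx <- toy_context()
  bd <- cost_cohort(generate_cohort(cfg), ctx)
  expect_identical(nrow(bd), 40L)
  component_sum <- sum(bd$physician) + sum(bd$nursing) + sum(bd$medication) +
    sum(bd$laboratory) + sum(bd$inpatient) + sum(bd$capital_share) +
    nrow(bd) * ctx$outpatient_fixed_share
  expect_lt(abs(sum(bd$total) - component_sum) / component_sum, 1e-9)
})

test_that("errors carry the patient id", {
  ctx <- toy_context()
  rec <- patient_record(
    "P-BAD",
    dispenses = tibble::tibble(patient_id = "P-BAD", hosp_id = NA_character_,
                               drug_name = "Unobtainium", doses = 1L, day = 0L))
  expect_error(patient_total_cost(rec, ctx), "P-BAD",
               class = "microcost_costing_error")
})

test_that("death-censored component costs are averaged out within the arm", {
  bd <- tibble::tibble(
    patient_id = c("a", "b", "c"), arm_label = "arv",
    physician = c(10, 20, 2), nursing = 0, medication = 0, laboratory = 0,
    inpatient = 0, capital_share = 0,
    outpatient = c(10, 20, 2), total = c(10, 20, 2))
  flags <- tibble::tibble(patient_id = "c", component = "physician")
  out <- impute_missing_visit_costs(bd, flags)
  expect_equal(out$physician, c(10, 20, 15))
  expect_equal(out$total, c(10, 20, 15))
  # imputed arm mean equals the complete-case mean
  expect_equal(mean(out$physician), mean(c(10, 20)))
  # untouched without flags
  expect_identical(impute_missing_visit_costs(bd, flags[0, ]), bd)
  # every value flagged: nothing to average
  all_flags <- tibble::tibble(patient_id = c("a", "b", "c"),
                              component = "physician")
  expect_error(impute_missing_visit_costs(bd, all_flags), "every value")
  expect_error(impute_missing_visit_costs(
    bd, tibble::tibble(patient_id = "a", component = "tea")), "tea")
})
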