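# Shared fixtures and independent oracles, built in code.

toy_price_table <- function() {
  unit_cost_table(tibble::tibble(
    item_name = c("DrugA", "DrugB", "TestX", "TestY"),
    dosage = c("0.5 g", NA, NA, NA),
    unit_price = c(0.5, 2.25, 4, 1.5),
    category = c("oi_drug", "arv", "lab_test", "lab_test")
  ))
}

toy_wages <- function() {
  wage_schedule(
    physician = list(monthly_wage = 1200, monthly_hours = 160, visit_duration = 0.5),
    nurse = list(monthly_wage = 480, monthly_hours = 160, visit_duration = 0.25)
  )
}

toy_context <- function(per_day_rate = 10, capital_share = 2,
                        outpatient_fixed_share = 1, flat_rate = 15) {
  costing_context(toy_price_table(), wages = toy_wages(),
                  per_day_rate = per_day_rate, capital_share = capital_share,
                  outpatient_fixed_share = outpatient_fixed_share,
                  lab_pricing = list(mode = "flat", flat_rate = flat_rate))
}

# A random patient record with at most 10 events across all streams.
random_small_record <- function(seed) {
  set.seed(seed)
  n_visit <- sample(0:3, 1)
  n_disp <- sample(0:3, 1)
  n_hosp <- sample(0:2, 1)
  n_lab <- sample(0:2, 1)
  hosp_ids <- if (n_hosp > 0) sprintf("P1-H%02d", seq_len(n_hosp)) else character()
  hosp_disp_n <- if (n_hosp > 0) sample(0:1, n_hosp, replace = TRUE) else integer()
  patient_record(
    patient_id = "P1", arm_label = "arv", followup_days = 50,
    visits = tibble::tibble(
      patient_id = "P1", day = sample(0:50, n_visit, replace = TRUE),
      cadre = sample(c("physician", "nurse"), n_visit, replace = TRUE),
      duration = round(runif(n_visit, 0.1, 1), 2), setting = "outpatient"),
    hospitalisations = tibble::tibble(
      patient_id = "P1", hosp_id = hosp_ids,
      start_day = sample(0:50, n_hosp, replace = TRUE),
      length_of_stay = sample(1:12, n_hosp, replace = TRUE),
      cause = rep("Pneumonia", n_hosp)),
    dispenses = dplyr::bind_rows(
      tibble::tibble(
        patient_id = "P1", hosp_id = NA_character_,
        drug_name = sample(c("DrugA", "DrugB"), n_disp, replace = TRUE),
        doses = sample(0:20, n_disp, replace = TRUE),
        day = sample(0:50, n_disp, replace = TRUE)),
      tibble::tibble(
        patient_id = "P1", hosp_id = rep(hosp_ids, hosp_disp_n),
        drug_name = rep("DrugA", sum(hosp_disp_n)),
        doses = sample(1:5, sum(hosp_disp_n), replace = TRUE),
        day = rep(0L, sum(hosp_disp_n)))),
    lab_tests = tibble::tibble(
      patient_id = "P1",
      test_name = sample(c("TestX", "TestY"), n_lab, replace = TRUE),
      day = sample(0:50, n_lab, replace = TRUE))
  )
}

# Independent brute-force costing oracle: prices every event one at a time
# with linear scans and plain arithmetic, sharing no code with the engine.
brute_force_total <- function(record, ctx) {
  price_of <- function(name, table) {
    for (k in seq_len(nrow(table))) {
      if (tolower(trimws(table$item_name[k])) == tolower(trimws(name))) {
        return(table$unit_price[k])
      }
    }
    stop("no price for ", name)
  }
  total <- 0
  v <- record$visits
  for (k in seq_len(nrow(v))) {
    if (v$setting[k] != "outpatient") next
    w <- ctx$wages[[v$cadre[k]]]
    total <- total + w$monthly_wage / w$monthly_hours * v$duration[k]
  }
  d <- record$dispenses
  for (k in seq_len(nrow(d))) {
    if (is.na(d$hosp_id[k])) {
      total <- total + d$doses[k] * price_of(d$drug_name[k], ctx$price_table)
    }
  }
  if (ctx$lab_pricing$mode == "flat") {
    total <- total + ctx$lab_pricing$flat_rate
  } else {
    for (k in seq_len(nrow(record$lab_tests))) {
      total <- total + price_of(record$lab_tests$test_name[k],
                                ctx$lab_pricing$lab_price_table)
    }
  }
  h <- record$hospitalisations
  for (k in seq_len(nrow(h))) {
    total <- total + h$length_of_stay[k] * ctx$per_day_rate
    for (j in seq_len(nrow(d))) {
      if (!is.na(d$hosp_id[j]) && d$hosp_id[j] == h$hosp_id[k]) {
        total <- total + d$doses[j] * price_of(d$drug_name[j], ctx$price_table)
      }
    }
  }
  total + ctx$capital_share + ctx$outpatient_fixed_share
}

# md5 of every file in a directory, named by relative path.
dir_checksums <- function(dir) {
  files <- sort(dir(dir, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", dir, "/?"), "", files)
  sums
}
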