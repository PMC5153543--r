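# End-to-end pipeline: validate a configuration, generate (or load) the
# cohorts, cost them, summarise them, and write a report bundle with full
# config and seed provenance. Every stage error is re-raised with the stage
# name so a failed run is attributable, and reruns with the same config and
# seed are byte-identical.

run_config_keys <- c("seed", "arms", "prices", "oi_table", "overhead",
                     "wages", "lab", "outpatient_fixed_share", "bootstrap",
                     "cpi")

#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) run configuration, checks it against the strict
#' schema — unknown top-level keys, missing sections, invalid arm fields and
#' unreadable referenced files are all violations — and returns either the
#' validated configuration or the full list of violations.
#'
#' @param path Configuration file path.
#' @return On success, a `run_config` list (with resolved absolute paths and
#'   parsed arm configurations). On failure, an error whose message lists
#'   every violation found.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(paste0("cannot parse config ", path,
                                                   ": ", conditionMessage(e))))
  violations <- character()
  note <- function(msg) violations[[length(violations) + 1]] <<- msg

  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown) > 0) {
    note(paste0("unknown top-level key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in c("seed", "arms", "prices")) {
    if (is.null(raw[[key]])) note(paste0("missing required key: ", key))
  }

  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
    if (!file.exists(p)) note(paste0("referenced file not found: ", p))
    p
  }

  arms <- list()
  if (!is.null(raw$arms)) {
    oi_path <- resolve(raw$oi_table)
    oi_tab <- if (!is.null(oi_path) && file.exists(oi_path)) {
      readr::read_csv(oi_path, col_types = "ci", progress = FALSE)
    } else {
      NULL
    }
    for (i in seq_along(raw$arms)) {
      arm_raw <- raw$arms[[i]]
      arm_raw$oi_frequency_table <- oi_tab
      cfg <- tryCatch(do.call(arm_config, arm_raw), error = function(e) {
        note(paste0("arms[", i, "]: ", conditionMessage(e)))
        NULL
      })
      if (!is.null(cfg)) arms[[length(arms) + 1]] <- cfg
    }
  }

  prices <- purrr::map_chr(raw$prices$drug_tables %||% character(), resolve)
  if (length(prices) == 0) note("prices$drug_tables must list at least one CSV")

  overhead <- raw$overhead
  if (!is.null(overhead)) {
    overhead$ledger <- resolve(overhead$ledger)
    overhead$assets <- resolve(overhead$assets)
  }

  if (length(violations) > 0) {
    abort(paste0("invalid configuration (", length(violations), " violation",
                 if (length(violations) > 1) "s" else "", "):\n- ",
                 paste(violations, collapse = "\n- ")),
          class = "microcost_config_error")
  }

  structure(list(
    seed = as.integer(raw$seed),
    arms = arms,
    price_paths = prices,
    overhead = overhead,
    wages = raw$wages,
    lab = raw$lab %||% list(mode = "flat", flat_rate = 15),
    outpatient_fixed_share = raw$outpatient_fixed_share %||% 0,
    bootstrap = raw$bootstrap %||% list(n_resamples = 10000, level = 0.95),
    source_path = normalizePath(path)
  ), class = "run_config")
}

# Combine several price CSVs into one lookup table (names must not collide).
combine_price_tables <- function(paths) {
  tabs <- purrr::map(paths, function(p) tibble::as_tibble(load_price_table(p)))
  unit_cost_table(dplyr::bind_rows(tabs),
                  source_label = paste(basename(paths), collapse = "+"))
}

# Build the costing context a validated config describes.
context_from_config <- function(config) {
  price_table <- combine_price_tables(config$price_paths)

  wages <- if (is.null(config$wages)) wage_schedule() else {
    wage_schedule(physician = config$wages$physician, nurse = config$wages$nurse)
  }

  per_day_rate <- 0
  capital_share <- 0
  oh <- config$overhead
  if (!is.null(oh)) {
    ledger <- load_overhead_ledger(oh$ledger)
    shares <- c(space_share = oh$space_share %||% 0,
                patient_load_share = oh$patient_load_share %||% 0)
    basis_by_line <- oh$basis_by_line %||%
      setNames(rep("space_share", length(ledger)), names(ledger))
    weights <- purrr::map_dbl(names(ledger), function(line) {
      shares[[basis_by_line[[line]] %||% "space_share"]]
    })
    allocated <- allocate_overhead(ledger, setNames(weights, names(ledger)))
    per_day_rate <- per_day_overhead_rate(sum(allocated), oh$bed_days_per_year)

    assets <- load_asset_register(oh$assets)
    horizon_years <- (oh$horizon_weeks %||% 96) * 7 / 365.25
    n_total <- sum(purrr::map_int(config$arms, "n_patients"))
    capital_share <- capital_share_per_patient(
      assets, weight = oh$capital_weight %||% oh$space_share %||% 0,
      n_patients = n_total,
      rate = oh$annuity_rate %||% 0.03, horizon_years = horizon_years)
  }

  lab <- config$lab
  lab_pricing <- if (identical(lab$mode, "per_test")) {
    list(mode = "per_test",
         lab_price_table = load_price_table(lab$lab_price_table))
  } else {
    list(mode = "flat", flat_rate = lab$flat_rate %||% 15)
  }

  costing_context(price_table = price_table, wages = wages,
                  per_day_rate = per_day_rate, capital_share = capital_share,
                  outpatient_fixed_share = config$outpatient_fixed_share,
                  lab_pricing = lab_pricing)
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)),
          class = "microcost_stage_error")
  })
}

#' Run the full costing pipeline
#'
#' Generates every configured arm's synthetic cohort, costs it, summarises
#' it, and writes the report bundle to `out_dir`:
#' cohort CSVs per arm (`cohort_<arm>/`), per-patient cost breakdowns
#' (`breakdowns.csv`, report-rounded to 2 decimals), an arm-by-component
#' summary with bootstrap CIs for mean costs (`summary_table.csv`), the
#' tabulated hospitalisation causes (`oi_frequency.csv`), mortality rates
#' (`mortality.csv`), a JSON results summary (`summary.json`), and a
#' `manifest.json` recording the configuration hash, seed and package
#' version. Outputs are a pure function of (configuration, seed).
#'
#' @param config Path to a YAML configuration or a validated `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configuration's master seed.
#' @return Invisibly, a list with the in-memory `breakdowns`, `summary`,
#'   `oi_table` and the output paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- with_stage("validate", {
    if (inherits(config, "run_config")) config else validate_config(config)
  })
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohorts <- with_stage("generate", {
    purrr::imap(config$arms, function(arm_cfg, i) {
      # Arm substreams are offset so arms never share a random stream.
      arm_cfg$seed <- as.integer((as.double(config$seed) + 104729 * i) %% 2147483647)
      cohort <- generate_cohort(arm_cfg)
      write_cohort(cohort, file.path(out_dir, paste0("cohort_", arm_cfg$arm_label)))
      cohort
    })
  })

  ctx <- with_stage("cost", context_from_config(config))
  breakdowns <- with_stage("cost", {
    dplyr::bind_rows(purrr::map(cohorts, cost_cohort, ctx = ctx))
  })
  report <- breakdowns
  num_cols <- vapply(report, is.numeric, logical(1))
  report[num_cols] <- lapply(report[num_cols], round_half_up, digits = 2)
  readr::write_csv(report, file.path(out_dir, "breakdowns.csv"))

  results <- with_stage("summarise", {
    bs <- config$bootstrap
    summary_tab <- cohort_summary_table(
      breakdowns, bootstrap = TRUE,
      n_resamples = bs$n_resamples %||% 10000, level = bs$level %||% 0.95,
      seed = config$seed)
    causes <- unlist(purrr::map(cohorts, function(co) co$hospitalisations$cause))
    oi_tab <- if (length(causes) > 0) oi_frequency_table(causes) else NULL
    mortality <- purrr::map_dfr(cohorts, function(co) {
      tibble::tibble(
        arm_label = co$patients$arm_label[1],
        n = nrow(co$patients),
        deaths = sum(!is.na(co$patients$death_day)),
        mortality_percent = round_half_up(
          mortality_rate(sum(!is.na(co$patients$death_day)), nrow(co$patients)), 2))
    })
    list(summary = summary_tab, oi_table = oi_tab, mortality = mortality)
  })

  with_stage("report", {
    summary_out <- results$summary
    num <- vapply(summary_out, is.numeric, logical(1)) &
      !names(summary_out) %in% "n"
    summary_out[num] <- lapply(summary_out[num], round_half_up, digits = 2)
    readr::write_csv(summary_out, file.path(out_dir, "summary_table.csv"))
    if (!is.null(results$oi_table)) {
      readr::write_csv(results$oi_table, file.path(out_dir, "oi_frequency.csv"))
    }
    readr::write_csv(results$mortality, file.path(out_dir, "mortality.csv"))
    jsonlite::write_json(
      list(summary = summary_out, mortality = results$mortality),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

    config_copy <- file.path(out_dir, "config_used.yaml")
    file.copy(config$source_path, config_copy, overwrite = TRUE)
    manifest <- list(
      config_file = basename(config$source_path),
      config_md5 = unname(tools::md5sum(config_copy)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("microcost")),
      outputs = setdiff(dir(out_dir, recursive = TRUE),
                        c("manifest.json"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(breakdowns = breakdowns, summary = results$summary,
                 oi_table = results$oi_table, mortality = results$mortality,
                 out_dir = out_dir))
}
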