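# Access to the bundled plain-text fixtures.

#' Path to a bundled example file
#'
#' The package ships small plain-text inputs under `extdata/`:
#' \describe{
#'   \item{`arv_unit_prices.csv`}{published per-dose prices of the trial
#'     antiretroviral formulations (fixed-dose combinations and components).}
#'   \item{`oi_drug_unit_prices.csv`}{published per-dose prices of
#'     cotrimoxazole prophylaxis and opportunistic-infection medications.}
#'   \item{`oi_staging_conditions.csv`}{recorded paediatric HIV staging
#'     conditions with observed frequencies (23 conditions, 751 events); the
#'     default opportunistic-infection table of the synthetic generator.}
#'   \item{`hospitalisation_causes.csv`}{recorded causes of hospitalisation
#'     with observed frequencies and the percentages as originally printed
#'     (which imply a slightly different base than the frequency total —
#'     kept verbatim; recompute percentages from the counts for analysis).}
#'   \item{`cpi_series_template.csv`}{header-only template for a US consumer
#'     price index series (`year,index`); values are an external statistic
#'     the analyst supplies.}
#'   \item{`demo_overhead_ledger.csv`, `demo_capital_assets.csv`}{synthetic
#'     demonstration ledgers for a facility of plausible scale.}
#'   \item{`demo_config.yaml`}{a complete two-arm pipeline configuration
#'     wired to the fixtures above.}
#' }
#'
#' @param file File name; with no argument, lists the available files.
#' @return Absolute path to the file.
#' @export
microcost_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "microcost")))
  }
  path <- system.file("extdata", file, package = "microcost")
  if (path == "") abort(paste0("no bundled example file called ", file))
  path
}

#' Bundled opportunistic-infection condition table
#'
#' The recorded paediatric HIV staging conditions and their observed
#' frequencies, used as the default cause table of the synthetic generator.
#'
#' @return Tibble with columns `condition` and `frequency`.
#' @export
oi_condition_table <- function() {
  readr::read_csv(microcost_example("oi_staging_conditions.csv"),
                  col_types = "ci", progress = FALSE)
}
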