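# Unit-price tables and price arithmetic.
#
# Prices follow the "ingredients" convention: each table row is one priced
# dose/test/unit in US$, looked up by a case-insensitive, whitespace-
# normalised item name. Lookups fail loudly — an unpriced item is an error,
# never a silent zero.

#' Load and validate a unit-price table
#'
#' Reads a CSV with columns `item_name`, `dosage`, `unit_price`, `category`
#' (categories: `arv`, `oi_drug`, `lab_test`, `other`). The bundled fixtures
#' `arv_unit_prices.csv` and `oi_drug_unit_prices.csv` (see
#' [microcost_example()]) carry the published per-dose prices of the trial
#' antiretrovirals and of the cotrimoxazole/opportunistic-infection
#' medications.
#'
#' @param path CSV file path.
#' @param currency_year Calendar year the prices are expressed in.
#' @param source_label Free-text provenance note.
#' @return A `unit_cost_table`: a tibble of price entries with attributes
#'   `currency_year` and `source_label`.
#' @export
#' @examples
#' tab <- load_price_table(microcost_example("oi_drug_unit_prices.csv"))
#' course_cost(data.frame(drug_name = "Cotrimoxazole", doses = 100), tab)
load_price_table <- function(path, currency_year = NA_integer_,
                             source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("price table not found: ", path))
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("item_name", "dosage", "unit_price", "category")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("price table ", path, " is missing header(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab$unit_price <- suppressWarnings(as.numeric(tab$unit_price))
  tab$dosage[tab$dosage == ""] <- NA_character_
  unit_cost_table(tab, currency_year = currency_year, source_label = source_label)
}

#' @rdname load_price_table
#' @param entries Data frame with the four price-entry columns.
#' @export
unit_cost_table <- function(entries, currency_year = NA_integer_,
                            source_label = "") {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) abort("price table must be nonempty")
  if (any(is.na(entries$unit_price))) {
    bad <- entries$item_name[is.na(entries$unit_price)]
    abort(paste0("non-numeric unit_price for item(s): ", paste(bad, collapse = ", ")))
  }
  if (any(entries$unit_price < 0)) {
    bad <- entries$item_name[entries$unit_price < 0]
    abort(paste0("negative unit_price for item(s): ", paste(bad, collapse = ", ")))
  }
  key <- norm_name(entries$item_name)
  if (anyDuplicated(key)) {
    dup <- unique(entries$item_name[key %in% key[duplicated(key)]])
    abort(paste0("duplicate item(s) in price table: ", paste(dup, collapse = ", ")))
  }
  structure(entries, class = c("unit_cost_table", class(entries)),
            currency_year = currency_year, source_label = source_label)
}

#' Write a unit-price table back to CSV
#'
#' Inverse of [load_price_table()]: round-tripping a table through
#' `load_price_table()` and `write_price_table()` reproduces the CSV
#' byte-identically.
#'
#' @param table A `unit_cost_table`.
#' @param path Output CSV path.
#' @export
write_price_table <- function(table, path) {
  out <- tibble::as_tibble(table)[, c("item_name", "dosage", "unit_price", "category")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# Vectorised price lookup; errors name every unknown item.
lookup_unit_price <- function(items, table, what = "item") {
  key <- norm_name(table$item_name)
  idx <- match(norm_name(items), key)
  if (anyNA(idx)) {
    unknown <- unique(items[is.na(idx)])
    abort(paste0("unpriced ", what, "(s): ", paste(unknown, collapse = ", ")))
  }
  table$unit_price[idx]
}

#' Cost of a course of medication
#'
#' Values each dispense at doses times the drug's unit price and sums over
#' the dispense list — the micro-costing treatment of a drug course.
#'
#' @param dispenses Data frame with columns `drug_name` and `doses`.
#' @param table A `unit_cost_table` pricing every dispensed drug.
#' @return Total cost in the table's currency (0 for an empty list).
#' @export
course_cost <- function(dispenses, table) {
  if (is.null(dispenses) || nrow(dispenses) == 0) return(0)
  if (any(dispenses$doses < 0)) abort("doses must be >= 0")
  prices <- lookup_unit_price(dispenses$drug_name, table, what = "drug")
  sum(dispenses$doses * prices)
}

#' Cost of a set of laboratory tests
#'
#' Sums the unit price of every test performed.
#'
#' @param tests Character vector of test names, or a data frame with a
#'   `test_name` column.
#' @param table A `unit_cost_table` pricing every test.
#' @return Total cost (0 for no tests).
#' @export
lab_panel_cost <- function(tests, table) {
  if (is.data.frame(tests)) tests <- tests$test_name
  if (length(tests) == 0) return(0)
  sum(lookup_unit_price(tests, table, what = "lab test"))
}

#' Consumer-price-index series
#'
#' `load_cpi_series()` reads a two-column CSV (`year`, `index`); the package
#' bundles only an editable header template (`cpi_series_template.csv`)
#' because index values are an external statistic the analyst supplies.
#' `cpi_adjust()` re-expresses a cost in a target year's prices by the ratio
#' of index values, the standard multiplicative (and hence invertible)
#' inflation adjustment.
#'
#' @param path CSV with columns `year` and `index`.
#' @return `load_cpi_series()`: a named numeric vector indexed by year.
#' @export
load_cpi_series <- function(path) {
  tab <- readr::read_csv(path, col_types = "id", progress = FALSE)
  if (!all(c("year", "index") %in% names(tab))) {
    abort("CPI series CSV must have columns year and index")
  }
  cpi_series(setNames(tab$index, tab$year))
}

#' @rdname load_cpi_series
#' @param series Named numeric vector (names are years, values index levels).
#' @export
cpi_series <- function(series) {
  if (length(series) == 0) abort("CPI series must be nonempty")
  if (any(!is.finite(series)) || any(series <= 0)) {
    abort("CPI index values must be positive")
  }
  structure(as.numeric(series), names = names(series), class = "cpi_series")
}

#' @rdname load_cpi_series
#' @param cost Cost in `from_year` prices.
#' @param series A `cpi_series` (or named numeric vector).
#' @param from_year,to_year Calendar years present in the series.
#' @export
cpi_adjust <- function(cost, series, from_year, to_year) {
  for (yr in c(from_year, to_year)) {
    if (!as.character(yr) %in% names(series)) {
      abort(paste0("year ", yr, " not present in CPI series"))
    }
  }
  cost * series[[as.character(to_year)]] / series[[as.character(from_year)]]
}
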