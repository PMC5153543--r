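# Cohort-level results surface: descriptive cost statistics, skewness
# diagnostics, percentile-bootstrap confidence intervals for mean costs,
# opportunistic-infection frequency tables, and mortality rates.
#
# Per-patient cost distributions in chronic disease are heavily right-skewed
# (a few patients consume a disproportionate share of resources), so the
# arithmetic mean — the policy-relevant statistic, since mean times cohort
# size is the budget — is reported with bootstrap rather than normal-theory
# intervals.

#' Descriptive summary of a cost vector
#'
#' Sample mean, standard deviation (n - 1 denominator), minimum and maximum.
#'
#' @param costs Nonempty numeric vector.
#' @return One-row tibble with `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarise_costs <- function(costs) {
  if (length(costs) == 0 || anyNA(costs)) {
    abort("costs must be a nonempty numeric vector without missing values")
  }
  tibble::tibble(
    n = length(costs),
    mean = mean(costs),
    sd = if (length(costs) > 1) sd(costs) else 0,
    min = min(costs),
    max = max(costs)
  )
}

#' Adjusted Fisher–Pearson sample skewness
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` where `g1 = m3 / m2^(3/2)` are the
#' biased moment estimators — the small-sample-corrected skewness reported
#' by standard statistical software.
#'
#' @param costs Numeric vector, `n >= 3`, non-degenerate.
#' @return Dimensionless skewness.
#' @export
skewness <- function(costs) {
  n <- length(costs)
  if (n < 3) abort("skewness requires at least 3 observations")
  d <- costs - mean(costs)
  m2 <- mean(d^2)
  if (m2 == 0) abort("skewness undefined for a constant sample")
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Percentile-bootstrap confidence interval for a mean cost
#'
#' Resamples the cost vector with replacement `n_resamples` times, takes the
#' mean of each resample, and returns the percentile interval of the
#' resampled means. Deterministic given `seed`.
#'
#' @param costs Nonempty numeric vector.
#' @param n_resamples Bootstrap replicates (default 10,000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed.
#' @return A `bootstrap_result` list: `point_estimate` (sample mean),
#'   `ci_low`, `ci_high`, `n_resamples`, `level`, `seed`.
#' @export
bootstrap_mean_ci <- function(costs, n_resamples = 10000, level = 0.95,
                              seed = 1L) {
  if (length(costs) == 0) abort("costs must be nonempty")
  assert_scalar_number(n_resamples, "n_resamples", min = 1, integerish = TRUE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("level must lie strictly between 0 and 1")
  }
  set.seed(seed)
  n <- length(costs)
  # One draw of all resample indices, reshaped: fast and stream-stable.
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n_resamples)
  means <- rowMeans(matrix(costs[idx], nrow = n_resamples))
  alpha <- 1 - level
  ci <- unname(quantile(means, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(list(point_estimate = mean(costs), ci_low = ci[1], ci_high = ci[2],
                 n_resamples = as.integer(n_resamples), level = level,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' Opportunistic-infection frequency table
#'
#' Tabulates condition counts and percentages (100 × count / total). Accepts
#' either raw condition labels (counted in order of first appearance) or a
#' precomputed count table; percentages are always recomputed from the
#' counts.
#'
#' @param causes Character vector of condition labels, or a data frame with
#'   columns `condition` and `frequency`.
#' @param digits Decimal places for the reported percent column (half-up
#'   rounding applied at report time only).
#' @return Tibble with columns `condition`, `frequency`, `percent`.
#' @export
oi_frequency_table <- function(causes, digits = 2) {
  if (is.data.frame(causes)) {
    if (!all(c("condition", "frequency") %in% names(causes))) {
      abort("count input must have columns condition and frequency")
    }
    counts <- causes
  } else {
    if (length(causes) == 0) abort("causes must be nonempty")
    counts <- tibble::tibble(
      condition = unique(causes),
      frequency = as.integer(table(factor(causes, levels = unique(causes))))
    )
  }
  if (nrow(counts) == 0) abort("causes must be nonempty")
  total <- sum(counts$frequency)
  if (total <= 0) abort("frequencies must sum to a positive total")
  tibble::tibble(
    condition = counts$condition,
    frequency = counts$frequency,
    percent = round_half_up(100 * counts$frequency / total, digits)
  )
}

#' Cumulative mortality as a percentage
#'
#' @param deaths Number of deaths (0 <= deaths <= n).
#' @param n Cohort size (> 0).
#' @return `100 * deaths / n`.
#' @export
#' @examples
#' mortality_rate(186, 265 + 269)  # pooled two-year mortality, ~35%
#' mortality_rate(22, 211)         # ARV cohort, ~10.4%
mortality_rate <- function(deaths, n) {
  assert_scalar_number(n, "n", min = 1, integerish = TRUE)
  assert_scalar_number(deaths, "deaths", min = 0, max = n, integerish = TRUE)
  100 * deaths / n
}

#' Ratio of mean costs between two summaries
#'
#' @param summary_a,summary_b One-row summaries from [summarise_costs()]
#'   (or any lists with a `mean` element).
#' @return `mean_a / mean_b`.
#' @export
cost_ratio <- function(summary_a, summary_b) {
  if (summary_b$mean == 0) abort("denominator mean is zero")
  summary_a$mean / summary_b$mean
}

#' Arm-by-component cost summary table
#'
#' Builds the standard results layout — one row per cost component per arm
#' with mean, SD, minimum and maximum — from a cohort breakdown tibble, with
#' optional percentile-bootstrap CIs for the means.
#'
#' @param breakdowns Tibble from [cost_cohort()] (may pool several arms).
#' @param components Components to summarise (default: all).
#' @param bootstrap If `TRUE`, attach `ci_low`/`ci_high` columns.
#' @param n_resamples,level,seed Bootstrap settings, see
#'   [bootstrap_mean_ci()].
#' @return Tibble with columns `arm_label`, `component`, `n`, `mean`, `sd`,
#'   `min`, `max` (and CI columns when requested).
#' @export
cohort_summary_table <- function(breakdowns,
                                 components = c("physician", "nursing",
                                                "medication", "laboratory",
                                                "inpatient", "outpatient",
                                                "capital_share", "total"),
                                 bootstrap = FALSE, n_resamples = 10000,
                                 level = 0.95, seed = 1L) {
  rows <- list()
  for (arm in unique(breakdowns$arm_label)) {
    sub <- breakdowns[breakdowns$arm_label == arm, ]
    for (comp in components) {
      row <- summarise_costs(sub[[comp]])
      row <- tibble::add_column(row, arm_label = arm, component = comp,
                                .before = 1)
      if (bootstrap) {
        bs <- bootstrap_mean_ci(sub[[comp]], n_resamples = n_resamples,
                                level = level, seed = seed)
        row$ci_low <- bs$ci_low
        row$ci_high <- bs$ci_high
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
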