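---
title: "Methods: trial-based micro-costing of paediatric HIV/AIDS treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based micro-costing of paediatric HIV/AIDS treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Costing evidence for paediatric HIV care in low-resource settings is built
alongside clinical trials: every resource a child consumes — physician and
nurse visits, hospital admissions, drug dispenses, laboratory tests — is
recorded on case-report forms (CRFs) and valued at its unit price. This
"ingredients" (micro-costing) approach sums, per patient,

* **labour** `L_i`: for each cadre, number of visits × (monthly wage /
  monthly contracted hours) × per-visit contact time;
* **capital** `K_t`: buildings, vehicles and laboratory equipment converted
  to an equivalent annual cost by the annuity factor
  `(1 − (1+r)^−n)/r`, apportioned to the programme, scaled to the analysis
  horizon and divided by the programme patient count;
* **medications** `D_d`: doses × per-dose unit price;
* **laboratory diagnostics** `L_l`: either a flat per-patient panel rate or
  per-test prices.

Hospital care is costed by the inpatient algorithm: direct cost (drugs
dispensed during the stay) plus overhead cost (length of stay × a
per-bed-day rate obtained by directly allocating the facility's shared-cost
ledger to the paediatric programme and dividing by annual bed-days).
Everything is from the provider perspective; patient and societal costs
(transport, caregiver time) are out of scope, as is currency conversion.
A consumer-price-index adjustment (`cpi_adjust()`) re-expresses costs in a
target year's prices by the ratio of index values; the index series itself
is an external statistic supplied by the analyst, so the package ships only
an editable template.

### Component accounting

`patient_total_cost()` reports physician, nursing, medication (outpatient
dispenses only), laboratory, inpatient, capital-share components and an
*outpatient* roll-up (labour + outpatient medication + laboratory +
apportioned fixed share). The roll-up repeats components that are already
counted, so the total is defined as the non-overlapping sum

```
total = physician + nursing + medication + laboratory
      + inpatient + outpatient_fixed_share + capital_share
```

Drugs dispensed during an admission are counted once, inside the inpatient
direct cost — never again under the medication component. This guard
matters because published component tables of this kind routinely fail to
sum to their printed totals precisely when hospital drug costs are
double-counted; the engine keeps the decomposition exact (conservation is
tested at 1e-9 relative tolerance).

## The synthetic cohort generator

Patient-level CRF data from the underlying trials are not publicly
available, so the generator is a first-class module that emulates the
statistical structure the costing stages assume. Its defaults encode the
two study arms:

* **cotrimoxazole preset** (`chap_arm_config()`): n = 265, 672-day
  (96-week) follow-up, cumulative mortality 186/534 — the pooled death count
  over both randomised groups (265 + 269; the published enrolment funnel is
  internally inconsistent, and 186/534 ≈ 35% matches the reported
  mortality) — length-of-stay cap 77 days;
* **ART preset** (`chapas_arm_config()`): n = 211, 336-day (48-week)
  follow-up, mortality 22/211 (the raw counts, ≈10.4%, are stored rather
  than the rounded "just under 10%" phrasing), stay cap 37 days.

Distributional choices where only ranges and means are published, chosen
once as field-plausible shapes and not revisited:

* visit counts and admission episodes per patient are **Poisson**
  (physician rates 14.2/11.0 and nurse rates 8.0/0.65 in the ART and
  cotrimoxazole presets, the values consistent with the published mean
  labour costs at the configured wage shares; admission rates 0.15 and 1.2
  reflect the reported much higher hospitalisation burden under
  cotrimoxazole);
* length of stay is **log-normal on the day scale, rounded up, truncated to
  [1, cap]** — the simplest shape that reproduces both the printed maximum
  stays and the right skew of cost totals; truncation by clamping puts the
  (tiny) excess mass on the cap, which is exactly where a hard recorded
  maximum concentrates it;
* the day of death is **uniform over follow-up** for children flagged to
  die (only cumulative mortality is published); all events after it are
  censored, and an admission straddling the death day is shortened so the
  stay ends on it — a deliberate refinement of plain event-dropping, since
  a patient cannot occupy a bed after death;
* admission causes are drawn from the bundled staging-condition table
  (23 conditions, 751 recorded events); dispenses during a stay are
  Poisson doses per drug of a configurable inpatient formulary, and study
  medication accrues per day alive (once-daily cotrimoxazole, twice-daily
  fixed-dose-combination ART).

Days are integer offsets from enrolment (day 0), closed interval; no date
convention is published, and integer days are what length-of-stay
arithmetic needs. Seeding uses one master seed with per-patient substreams
derived from (seed, patient index), so a fixed seed reproduces a cohort
byte-identically and enlarging a cohort never reshuffles earlier patients.

What the generator does **not** emulate: CD4 trajectories, growth, clinical
efficacy, seasonality, between-visit correlation, or informative censoring
(death is independent of accrued cost). Passing tests therefore demonstrate
that the *costing machinery* is correct under the stated stochastic
structure, not that real trial cohorts follow that structure.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| annuity rate | fraction/yr | 0.03 | standard discount rate for capital in this literature |
| building life | years | 40 | published infrastructure convention |
| vehicle/equipment life | years | 5 | published convention for non-building assets (read as covering laboratory equipment, configurable) |
| analysis horizon | weeks | 96 | trial duration used to scale annual capital to per-patient shares |
| wage shares | US$/visit | physician 5.00 / 2.00, nurse 2.00 (1600 or 640 per month, 160 h, 0.5 h/visit) | consistent with published mean labour costs at the configured visit rates |
| laboratory panel | US$/patient | 15, flat | the published laboratory component has zero spread, implying a flat per-patient panel; a per-test mode exists and the per-patient reading is configurable |
| bootstrap | — | B = 10,000, percentile, level 0.95 | bootstrapping is named without settings; percentile is the conventional default for skewed cost means |

Unit prices are read "one printed row = one priced dose unit". The
opportunistic-infection price table prints prices under a "Dosage" header;
the fixture stores those values as `unit_price` with dosage absent. Whether
antiretroviral prices are per tablet or per gram is not stated; the
one-dose-unit convention is a declared convention of this package, not an
inference. Name matching is case-insensitive and whitespace-normalised with
no fuzzy matching: an unpriced item is an error, never a silent zero.

## Missing data and censoring

Resource use not captured because of death is treated as missing and
"averaged out": `impute_missing_visit_costs()` replaces flagged component
values with the arm mean of non-missing values (the averaging level is not
published; arm-level is the choice here, and the flags are caller-supplied
so any other level can be expressed). Imputation preserves the
complete-case mean by construction. The regression alternative for censored
costs is a named non-goal.

## Numerical choices

* All arithmetic is double precision; report-level rounding is half-up to
  2 decimals and applied only at serialisation (`breakdowns.csv`,
  `summary_table.csv`, percent columns).
* The annuity factor uses the closed form with the exact `years` limit at
  rate 0; it is continuous there and strictly decreasing in rate (tested).
* Percentages always recompute from counts — no stored-percent drift. The
  bundled hospitalisation-cause table keeps its originally printed percents
  in a separate `printed_percent` column because they imply a slightly
  different base than the frequency total; analyses use the recomputed
  values. One duplicated condition label in that table is disambiguated as
  "(second listing)".
* Degenerate inputs fail loudly with the offending field, item or patient
  named: empty price tables, negative prices or doses, unknown cadres or
  drugs, zero denominators, all-missing imputation, skewness of constant
  samples.
* Bootstrap resampling draws all indices in one call and reshapes,
  making the CI deterministic in (data, seed, B).

## Problem sizes

The test suite generates cohorts of up to 10,000 patients for rate- and
mortality-recovery checks (3-standard-error bands), 100,000 draws for
opportunistic-infection frequency convergence, 1,000 Monte-Carlo replicates
with B = 2,000 for bootstrap coverage, and 20 master seeds × trial-sized
cohorts (211/265 patients) for labour-cost recovery; these sizes put the
Monte-Carlo error well below the tolerances tested while keeping the full
suite in the low minutes on one core. The parameter-recovery runs fix
mortality at zero so the estimand is exactly rate × wage share; censoring
behaviour is tested separately.

## Known limitations

* The percentile bootstrap undercovers for strongly skewed costs at modest
  n: the package's own coverage simulation (lognormal(0,1), n = 50,
  B = 2,000, 1,000 replicates) measures ≈ 89% for the nominal 95% interval,
  and the skew-corrected BCa variant is only marginally better there. For
  small, very skewed cohorts the intervals should be read as approximate;
  B can be raised and the interval method is isolated in
  `bootstrap_mean_ci()` if a bootstrap-t variant is ever needed.
* Published component means cannot be reproduced end-to-end because the
  underlying patient-level data are unavailable and the published component
  table does not sum to its printed totals; the package therefore
  reproduces the in-table arithmetic that is self-consistent (frequency
  percentages, mortality, ratio-of-means) and recovers configured
  rate × price products on synthetic cohorts instead.
* Only direct overhead allocation is implemented (stepdown and simultaneous
  allocation are explicit non-goals); cost-effectiveness ratios, QALYs and
  currency conversion are out of scope.
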