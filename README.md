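# pmexposure

Microenvironmental time-activity modelling of daily PM2.5 exposure.

## The problem

Measuring personal exposure to fine particulate matter (PM2.5) directly is
accurate but expensive, so it is usually done for a handful of subjects. An
indirect, population-scale alternative combines two cheaper data sources:

* **microenvironmental concentration measurements** — portable-monitor
  PM2.5 readings at 1-minute resolution, each tagged with the
  microenvironment it was taken in (residential indoor, transportation, or
  "other"); and
* **time-activity diaries** — for each person-day, which of those three
  microenvironments the person occupied in each of the 144 ten-minute slots
  of the day, as collected by national time-use surveys, together with
  demographic covariates.

`pmexposure` implements this model for exposure scientists and
environmental epidemiologists: it builds the 144-slot × 3-microenvironment
diurnal concentration grid, scores diary populations against it, simulates
population exposure distributions, and characterizes the high-exposure tail.

## The model

Daily personal exposure is the time-weighted average concentration

```
E = (1/144) * sum over t = 1..144 of C_t(m_t)
```

where `C_t(m)` is the concentration of microenvironment `m` in slot `t` and
`m_t` is the microenvironment the diary records for slot `t`. The package
supports both readings of `C_t(m)`:

* **deterministic** — `C_t(m)` is the empirical mean of the grid cell
  (`compute_exposure()` / `compute_exposures()`);
* **stochastic** — `C_t(m)` is a distribution fitted to the cell's 1-minute
  data (lognormal, gamma, Weibull or zero-truncated normal, selected by AIC
  or a KS statistic), sampled by Monte-Carlo over many trials
  (`fit_grid_distributions()` + `simulate_population()`).

Grid cells with too few observations are *unavailable*: diary slots falling
on them are excluded and the daily average is taken over the reduced time
base (a person in transit for 20 minutes during an unmeasured early-morning
window is averaged over 1420 rather than 1440 minutes).

The top 5% of the exposure distribution forms the high-exposure group,
characterized by Fisher's exact test / Welch's t-test screening (p < 0.1),
variance-inflation-factor pruning, and a multivariate logistic regression
with per-variable likelihood-ratio p-values and Wald odds-ratio intervals
(`label_top_fraction()`, `group_report()`).

Because national diary surveys and measurement campaigns are rarely
redistributable, the package ships generators (`generate_campaign()`,
`generate_population()`) that emulate their statistical structure —
diurnal lognormal concentration fields, block-structured commute/work/home
schedules with day-type-dependent time budgets, and covariates with
controllable effect sizes — so the whole pipeline is testable end to end.

## Worked example

```r
library(pmexposure)

## synthetic campaign (~59,000 one-minute records) and its concentration grid
records <- generate_campaign(campaign_spec(seed = 42))
grid    <- build_grid(records, min_obs_per_cell = 5)
grid    <- fit_grid_distributions(grid, criterion = "AIC")
grid
#> slot_grid: 144 slots x 3 microenvironments (432 cells)
#>   available cells: 409 of 432
#>   observations: 59053
#>   fitted cells: 409

## a 2000-person diary population, deterministic exposures
pop       <- generate_population(population_spec(n_subjects = 2000, seed = 43))
exposures <- compute_exposures(pop, grid)
s <- summarize_exposures(exposures$exposure, standard = 35)
#> mean 25.1, sd 2.3, median 24.1, p95 31.1 ug/m3; GM 25.0, GSD 1.09

## Monte-Carlo population simulation from the fitted cell distributions
simulate_population(pop, grid, n_trials = 2000, seed = 44)
#> simulation_summary: 2000 subjects x 2000 trials ( shared_per_cell )
#>   mean 25.35 +/- 3.91 ug/m3; median 24.61; p95 32.60; p99 38.43
#>   GM 25.09, GSD 1.15; exceedance of 35 ug/m3: 2.60%

## top-5% high-exposure group and its characterization
lab <- label_top_fraction(exposures, 0.05)
lab
#> group_labeling: high 100 / low 1900 (top 5.0%, threshold 31.1 ug/m3)
cov <- pop$covariates; cov$day_type <- as.character(pop$day_type)
rep <- group_report(lab, cov,
                    references = list(day_type = "weekday", job = "office",
                                      industry = "primary_secondary"))
rep$model
#>       variable      level coefficient    se    or ci_low ci_high
#>            job non_office       0.770 0.273 2.160  1.265   3.688
#>  working_hours       <NA>       0.007 0.007 1.007  0.994   1.021
#>  ...
```

Read: the deterministic person-day exposures centre near 25 µg/m³ with a
narrow spread (GSD 1.09) because each is already an average over 144 slot
means; the Monte-Carlo distribution is wider (sd ≈ 3.9 µg/m³) because it
propagates within-cell concentration variability, and about 2.6% of
simulated person-days exceed the 35 µg/m³ 24-h standard. In the group
model, non-office workers have roughly twice the odds of landing in the
high-exposure group — the effect built into this synthetic population.

`run_pipeline()` chains all stages from CSV inputs to CSV/JSON artifacts;
`inst/cli/pmexposure` exposes the same stages as shell subcommands
(`grid`, `budgets`, `estimate`, `simulate`, `synth`, `run`).

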