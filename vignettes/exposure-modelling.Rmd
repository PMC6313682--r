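---
title: "Microenvironmental time-activity modelling of daily PM2.5 exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microenvironmental time-activity modelling of daily PM2.5 exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmexposure)
```

## The model and its assumptions

Daily personal PM2.5 exposure is modelled as the time-weighted average of
microenvironmental concentrations over the 144 ten-minute slots of a day:

$$E \;=\; \frac{1}{144}\sum_{t=1}^{144} C_t(m_t),$$

where $m_t$ is the microenvironment a person's diary records for slot $t$
(residential indoor, transportation, or "other") and $C_t(m)$ is the
concentration of microenvironment $m$ in slot $t$. The model's assumptions
are worth stating plainly:

* **Microenvironmental homogeneity.** Within a slot, everyone in the same
  microenvironment category experiences the same concentration (or the same
  concentration distribution). The three-category scheme is coarse —
  "other" pools workplaces, restaurants and outdoor locations — so the
  model captures between-category and diurnal contrast, not within-category
  heterogeneity.
* **Diurnal stationarity.** All measurement days are pooled into a single
  24-hour grid; day-to-day concentration variation enters only through the
  per-cell distributions, not as a day effect.
* **No mass-balance physics.** Concentrations are measured, not derived
  from ambient data via infiltration modelling. This makes the model only
  as general as its measurement campaign.

## The concentration grid

`build_grid()` assigns each 1-minute record to slot
$t = \lfloor \text{minute}/10 \rfloor + 1$ (slots are 1-based; minutes are
0-based and half-open, so minutes 0–9 form slot 1) within its
microenvironment, giving a fixed 144 × 3 = 432-cell object regardless of
input. Gravimetric correction (`apply_correction()`) is a per-run positive
multiplier applied before gridding; negative input concentrations are
rejected at read time rather than clipped, since a portable optical monitor
cannot report them and they signal a parse error.

A cell is *available* when it holds at least `min_obs_per_cell`
observations (default 5). The threshold is the package's mechanism for the
empirically observed phenomenon that some slot/microenvironment
combinations (early-morning transit, typically) simply go unmeasured; five
observations is the least that makes a mean, an SD and a two-parameter
maximum-likelihood fit all defensible. Unavailable cells are never imputed:
diary slots landing on them are excluded and the exposure denominator
reduced (a 20-minute early-morning transit on empty cells gives an average
over 1420 rather than 1440 minutes). Imputation would silently borrow
strength across time of day exactly where the data say nothing.

## Per-cell distribution fitting

The simulation path needs a sampling distribution per cell.
`fit_cell_distribution()` fits lognormal, gamma and Weibull laws by maximum
likelihood via `fitdistrplus`, plus a zero-truncated normal fitted by
direct optimisation of the truncated likelihood, and keeps the family
minimising AIC (default) or the Kolmogorov–Smirnov statistic. These four
families cover right-skewed non-negative concentration data; exposure
distributions in this literature are repeatedly found close to lognormal,
and on the default synthetic campaign the lognormal indeed wins most cells.
Numerical care: the truncated normal's maximum can sit deep in the left
tail (large negative location, large scale — an effectively exponential
density on $[0,\infty)$), where naive `1 - pnorm(0, m, s)` underflows, so
its density, CDF, quantile and mean are all computed in survival/log form.
Zero-variance cells cannot support a continuous fit and fall back, with a
warning, to a point mass at the observed value; this degenerate family is
also what makes the simulation's deterministic limit exactly testable.

## Monte-Carlo population simulation

`simulate_population()` re-draws every used cell's concentration per trial
and recomputes each diary's exposure, with 10,000 trials as the default.
Two draw scopes exist because the natural reading is ambiguous: the default
`shared_per_cell` treats a trial as one realised day of microenvironment
conditions — a single draw per cell shared by all subjects occupying it
(432 draws per trial, computationally light); `independent_per_subject`
draws per subject. The per-subject *mean* over trials is identical in
expectation under both; the population spread per trial differs. Each cell
gets its own deterministically derived RNG substream
(`(seed mod 2·10^6)·1000 + cell index`, collision-free over the 432 cells
and below $2^{31}$), so changing the draw scope or the set of diaries never
perturbs another cell's draws, and a given seed is bit-reproducible.

An important distinction the tests enforce: as trials grow, the simulated
per-subject mean converges to the exposure computed from the *fitted
distributions' analytic means*, not from the raw cell means — a fitted
lognormal's mean is $e^{\mu + \sigma^2/2}$, which differs from the sample
mean in finite cells. Extreme draws are not truncated; with heavy-tailed
fitted cells, simulated maxima far above any observed concentration are
expected behaviour, not a bug.

Summaries (`summarize_exposures()`) report arithmetic and geometric means,
GSD, median and the 95th/99th percentiles (R's default linear-interpolation
quantile definition, type 7), the fraction of person-days strictly above an
exceedance standard (default 35 µg/m³, a 24-h fine-PM standard,
configurable), and a log-normality statistic: the probability-plot
correlation of log exposures against normal quantiles.

## High-exposure-group analysis

`label_top_fraction()` takes the `ceil(0.05 N)` highest exposures as the
high group — with $N = 8072$ this gives 404 versus 7668, matching the
ceiling convention. Ties at the cut are broken by input order under a
stable sort: deterministic and seed-free.

Screening conventions, each fixed because the underlying choice is
genuinely open:

* Categorical variables use Fisher's exact test with the
  probability-ordering two-sided convention (`stats::fisher.test`; tables
  beyond exact reach fall back to a seeded Monte-Carlo p-value with a
  reported standard error). Continuous variables use Welch's unequal
  variance t-test — the safer default when one group is 19 times the size
  of the other.
* Variables pass at p < 0.1 (strict inequality).
* `not_applicable` levels (industry/job for non-working respondents) are
  treated as missing variable-wise, so employment-only variables are tested
  and fitted on the employed subset.
* Collinearity is screened by per-term VIFs from auxiliary regressions
  ($1/(1-R^2)$), dropping the worst variable above the threshold (default
  10) iteratively; exact collinearity is resolved first by dropping the
  later-ordered duplicate.
* The "stepwise" element is screen-then-single-fit, not iterative add/drop
  elimination: the final logistic model retains every screened-in variable
  even if individually non-significant, which matches how such covariate
  tables are conventionally reported.

`fit_logistic()` is a maximum-likelihood `glm` with dummy coding against
explicit reference levels; per-variable p-values come from drop-one
likelihood-ratio refits, and odds-ratio intervals are Wald,
$\exp(\beta \pm 1.96\,\mathrm{SE})$, asserted to bracket
$\mathrm{OR} = e^\beta$. Non-convergence is an error; complete separation
and fewer than 10 events per parameter are warnings.
Scheffé's post-hoc test (used for day-type time-budget comparisons after
one-way ANOVA) refers each pairwise contrast's F to
$(k-1)F_{k-1,N-k}$ — computed directly from the ANOVA mean square since no
installed package exposes it; the construction is never less conservative
than the unadjusted contrast, which the tests check as a property.

## What the synthetic generators emulate — and what they don't

`generate_campaign()` draws lognormal 1-minute concentrations per cell
around an hourly profile. The defaults encode the study conditions this
model family targets: residential indoor averaging ≈ 23.7 µg/m³ with a
lunch-time bump, transportation ≈ 24.2 µg/m³ flat, "other" ≈ 34.7 µg/m³
with an 18:00–22:59 elevation; GSDs of 2.3/2.2/3.3 back-computed from
SD-to-mean ratios of about 1.0/0.94/1.8; 229/37/150 observations per cell
(≈ 59,900 minutes in total); and 23 blanked transportation cells spanning
02:10–06:00, which both reproduces the 409-of-432 availability structure
and activates the reduced-denominator rule for early commuters.

`generate_population()` draws a day-type mix of 4849:1608:1618
(weekday:Saturday:Sunday) and per-day-type budget triples — e.g. 13.95 ±
4.77 h residential on weekdays, 17.01 ± 5.40 h on Sundays. Component draws
are clipped at zero and renormalised to 24 h rather than truncated-normal
sampled: renormalisation keeps component means within ~0.15 h of their
targets, whereas truncating a normal with these SDs would bias the Sunday
residential mean down by over an hour. Schedules are block-structured
(home–commute–activity–commute–home, departure 07:00–09:10, or 04:20 for
the 5% early-transit minority), not slot-i.i.d., so transit appears as
morning/evening bands. Covariate effects (defaults: tertiary industry 1.0,
non-office job 0.8, 0.028 per weekly working hour, on the log-odds scale)
act by converting the *centred* linear predictor into extra "other" hours
(0.6 h per unit) traded against residential time; centring keeps budget
means on target so the effect machinery does not distort the day-type
calibration.

What passing tests on these populations do **not** show: real diary data
have within-category concentration heterogeneity, day-to-day correlation,
survey weighting, and joint covariate structure (age–employment–income
dependence) that the generators deliberately omit — they reproduce
marginal structure and controllable effects only. Parameter-recovery and
power results here certify the estimator machinery, not field performance.

## Numerical choices and degenerate inputs

* Report-table rounding is half-up (1 decimal for percentages, 3 for model
  terms), via `round_half_up()`, matching the convention of published
  characteristic tables; base R's banker's rounding is not used there.
* Empty grid cells are valid (unavailable); an all-unavailable diary is an
  explicit error, as is a diary with codes outside the three-category
  scheme (later seven-category survey codes are accepted only through the
  documented `map_seven_category()` mapping).
* Geometric summaries require strictly positive values and error otherwise;
  constant data yield GSD 1 and an undefined (NA) log-normality statistic.
* `fisher_exact()` rejects tables with an all-zero margin rather than
  returning p = 1.

## Problem sizes

The shipped tests run the full pipeline at reduced scale — populations of a
few hundred to 4000 diaries, simulations of $10^2$–$10^4$ trials,
50-replication recovery studies at $N = 8000$ — sizes chosen so the whole
suite completes in about two minutes while every stochastic check retains a
comfortable margin (3 Monte-Carlo SEs, pooled binomial envelopes). The
acceptance script runs the full 8072-person population with 2000 trials,
which reproduces all distributional summaries to well within Monte-Carlo
noise of the 10,000-trial default.

## Known limitations

* Three microenvironments cannot separate workplace from restaurant
  exposure; the "other" category carries most of the high-exposure signal.
* The grid pools all campaign days: no weekday/weekend or seasonal
  stratification of concentrations.
* Exposure, not dose: no inhalation rates, no deposited fraction.
* The deterministic path's population SD is narrow by construction (every
  subject averages the same 432 cell means); between-person contrast comes
  from time-activity differences alone.
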