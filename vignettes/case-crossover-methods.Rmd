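---
title: "Methods: time-stratified case-crossover analysis of air pollution and daily counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-stratified case-crossover analysis of air pollution and daily counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aircrossover)
```

## The design and the model

The package estimates short-term associations between a lagged daily
exposure (a pollutant concentration or a composite air-quality index)
and daily counts of acute health events.  The inferential device is
the time-stratified case-crossover design executed at the daily-count
level: every date is assigned to the calendar stratum
*year : month : day-of-week* (`build_time_strata()`), so each day is
compared only with the 3–4 other days of the same weekday in the same
month.  Any confounder that is constant within such a stratum —
long-term trend, seasonality, weekday patterns, slowly varying
population characteristics — is eliminated by design rather than by
modelling.

Within strata the daily counts are modelled as Poisson with log-rate

$$\log \mu_t \;=\; \alpha_{s(t)} \;+\; \beta\, x_{t-\ell} \;+\;
  f(\mathrm{temp}_{t-\ell}) \;+\; g(\mathrm{rh}_{t-\ell}),$$

where $\alpha_{s}$ is the stratum intercept, $x_{t-\ell}$ the exposure
lagged by $\ell \in \{0,\dots,14\}$ whole days, and $f$, $g$ natural
cubic splines of temperature and relative humidity lagged by the *same*
$\ell$.  Conditioning on the stratum totals $Y_s = \sum_{t\in s} y_t$
removes the $\alpha_s$ and leaves the conditional log-likelihood

$$\ell(\beta,\gamma) = \sum_s \Big[ \sum_{t \in s} y_t \eta_t
  - Y_s \log \sum_{t \in s} e^{\eta_t} \Big],
  \qquad \eta_t = \beta x_t + \gamma' z_t,$$

a within-stratum multinomial likelihood.  This conditional fit is
mathematically identical to an unconditional Poisson regression with
one indicator per stratum; the package exploits the identity as an
independent test oracle (`glm()` with stratum dummies) but never forms
the indicator matrix itself.

Key modelling assumptions: events are conditionally independent given
the daily covariates (no overdispersion correction, no outcome
autocorrelation beyond what the strata absorb); the exposure effect is
log-linear in concentration; one single-lag, single-pollutant model is
fitted per cell — distributed-lag and multi-pollutant models are out of
scope.

## Exposures: pollutants, AQHI, AQHIX, 8-h ozone

Measured exposures are daily city-level series (CO in ppm; NO2, O3,
SO2 in ppb; PM2.5 in µg/m³).  Units are declared per pollutant and
never converted implicitly; $\beta$ is always per one unit of the
declared scale, and `relative_risk()` converts a fit to a risk ratio
per chosen increment (the pollutant's interquartile range by default,
`iqr_increment()`, since a raw slope leaves the increment to the
reader).

The Air Quality Health Index is computed from its three constituents
as

$$\mathrm{AQHI} = \tfrac{10}{10.4} \times 100 \times
  \big[(e^{c_1 \mathrm{NO_2}} - 1) + (e^{c_2 \mathrm{O_3}} - 1)
     + (e^{c_3 \mathrm{PM_{2.5}}} - 1)\big]$$

with the published Canadian excess-mortality coefficients
$c_1 = 0.000871$, $c_2 = 0.000537$, $c_3 = 0.000487$
(`aqhi_coefficients()`; overridable).  AQHIX substitutes the daily
maximum 8-h ozone for the daily mean.  Two deliberate choices:

* the index is used **continuously**, never rounded to the operational
  1–10+ reporting bands — the models regress on concentration-scale
  exposures and rounding would only discard information;
* `daily_max_8h()` evaluates the 17 running 8-h windows that lie fully
  inside the calendar day (start hours 00:00–16:00), accepts a window
  when at least 6 of its 8 hours are observed, and declares the day
  missing when no window qualifies.  Cross-midnight windows are a
  defensible alternative; a convention had to be fixed, and this one is
  configurable at the validity-rule level and verified against a
  brute-force scan in the tests.

## Patient strata

`enumerate_patient_strata()` returns the fixed 18-row layout: 3
sex-only strata, 6 season-by-sex strata (warm = April–September,
cold = October–March) and 9 age-by-sex strata.  Age and season are
never crossed.  The elderly band starts at **61** (bands 0–10, 11–60,
61+), while the conventional row label remains "Age 60+": where the
textual band definition and the row label disagree, the package treats
the explicit band as authoritative and keeps the label cosmetic; the
cut points are configurable (`age_breaks`) for anyone preferring a
60+ band.

## Numerical choices in the fitter

`fit_conditional_poisson()` maximises the conditional log-likelihood
by Newton–Raphson:

* covariates are **centred within stratum** first — the conditional
  likelihood is invariant to adding any stratum-constant to $\eta$
  (verified numerically in the tests), and centring keeps the
  exponentials well scaled and the information matrix well
  conditioned;
* within-stratum softmax terms subtract the stratum maximum of
  $\eta$ before exponentiation;
* steps are halved whenever a full Newton step would decrease the
  likelihood; convergence is declared when the relative change in the
  conditional log-likelihood falls below $10^{-8}$, with a cap of 100
  iterations.  Non-convergence is flagged, never silently accepted;
* standard errors come from the inverse observed information at the
  optimum; `wald_p()` gives two-sided normal p-values.  Significance
  is **strict**: a cell is marked only when $\beta > 0$ *and*
  $p < 0.05$, so a p-value of exactly 0.05 is non-significant;
* degenerate adjustment columns (no within-stratum variation) are
  dropped and recorded; an exposure constant within every stratum is a
  hard "not identified" error;
* complete-case deletion handles missing exposure or weather days, and
  strata with zero total count or fewer than two days are removed —
  they contribute nothing to the conditional likelihood.

The spline dimension defaults to **3 df per weather variable** — a
common choice for daily time-series health models, small enough to
survive within-month conditioning — and is a configuration knob
recorded in the outputs; weather can also be adjusted linearly
(`df = 1`) or omitted (`spline_df = 0`).

## The synthetic-data generator

`sim_config()` plus `simulate_pollutants()`, `simulate_weather()` and
`simulate_counts()` generate a complete study with known truth:

* pollutants: annual sinusoid (period fixed at 365.25 days, phase per
  pollutant) plus stationary AR(1) noise, truncated at zero.  Default
  levels, amplitudes and autocorrelations are set once to values
  typical of an urban mid-latitude monitoring network (e.g. NO2 around
  20 ppb with winter peaks, O3 around 25 ppb peaking in summer,
  PM2.5 around 8 µg/m³);
* weather: sinusoidal temperature with Gaussian noise; relative
  humidity Gaussian truncated to [0, 100];
* counts: Poisson with the planted log-rate — baseline, seven
  day-of-week factors, the lagged log-linear exposure effect, smooth
  quadratic weather terms, and independent month-level intercept
  shifts that the time strata must absorb.  The planted parameters are
  recorded in the output metadata so recovery can be checked.  The
  strength of weather–count confounding is deliberately a **free
  parameter** (default: a mild U-shaped temperature term, no humidity
  term), since no canonical value exists for it;
* patient strata: a chapter-level count series is split into the six
  sex-by-age cells by a daily multinomial draw with fixed proportions
  (50/50 sex; 15/60/25 across ages), so subgroup counts sum exactly to
  the chapter total and season follows from the date;
* reproducibility: all draws use R's Mersenne-Twister stream, the
  generator name is recorded in the metadata sidecar, and identical
  configurations with identical seeds are bit-identical.  The seed
  contract is per implementation (same seed, same stream), not
  cross-language.

What the generator does **not** emulate: station-level measurement
error and averaging, diagnostic coding noise, real concentration
distributions of any particular city, holidays or epidemics.  Passing
parameter-recovery and type-I-error suites on these simulations
validates the estimation machinery, not the epidemiology of any real
dataset.

## Matrices and summaries

`build_binary_matrix()` marks each (stratum, lag) cell with 1 exactly
when the slope is positive and significant; negative, non-significant,
missing and non-converged cells are 0, with non-converged and missing
cells tallied separately in attributes so fit failures stay visible.
`sum_matrices()` adds the chapter-level matrices cellwise (0–12 with
twelve chapters); `count_summaries()` produces per-pollutant totals,
per-stratum row totals over the lags, row maxima, and the percentage
of positive results among all tested models.  Two percentage
conventions circulate for such tables — share of all fitted cells
versus a maximum-row-based figure — and published tables do not always
say which denominator they use; the summary therefore reports the
cell-count percentage (`total / (18 × 15 × chapters) × 100`) and
exposes the row maxima separately rather than guessing.

The significance threshold is a parameter, so the stricter
$p < 0.001$ sensitivity run reuses the same code path;
`persistence_ratio()` reports $100\,b/a$, the share of $p<0.05$
associations surviving at $p<0.001$.  Heatmap export uses a linear
green-to-red ramp with the numeric value printed in each cell — the
numbers, not the colours, are the contract.

## Pipeline and problem sizes

`run_full_analysis()` enumerates the grid in a fixed order (chapter,
pollutant, stratum, lag), fits every cell, and writes the flat results
CSV, the binary and summed matrix CSVs, heatmaps, the summary table,
the persistence report and a JSON run log.  Sparse cells (for example
a young-age stratum of a disease chapter with near-zero counts, or a
season stratum outside the simulated date range) are logged skips that
contribute 0 to the matrices, not errors.  Outputs depend only on the
configuration and seed, never on execution order.

The validation suites use deliberately desk-scale problem sizes chosen
as a package design decision: oracle-equivalence fixtures of 200 days;
parameter recovery with planted slopes $\beta \in \{0, 0.01, 0.05\}$
at lags $\{0, 3, 14\}$ on 1000-day series, 100 replicates per
combination; the null positive-significance rate (nominally
$0.05/2 = 0.025$, because marking requires the positive sign *and*
two-sided significance) over 500 replicates of 600-day series; and an
end-to-end acceptance run of twelve chapters over one year of daily
data.  At these sizes every statistical check runs comfortably on a
laptop while the binomial error bounds remain tight enough to be
informative.

## Known limitations

* No overdispersion or outcome-autocorrelation correction; the
  conditional Poisson variance is taken at face value.
* Many cells are tested and no multiplicity correction is applied
  beyond the two fixed thresholds — matrix counts are descriptive
  screening summaries, not confirmatory inference.
* Single-lag models only; neighbouring-lag results are correlated
  because the underlying exposure series is autocorrelated, so rows of
  the matrices must be read as profiles, not independent tests.
* The 8-h-maximum window convention and the AQHI coefficients are
  fixed (though overridable) choices; analyses feeding in externally
  computed O3H8 or index series bypass both.
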