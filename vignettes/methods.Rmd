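---
title: "Methods: urban-rural analysis of experience-sampled hay fever diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urban-rural analysis of experience-sampled hay fever diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollendiary)
library(dplyr)
```

## The analysis pipeline

`pollendiary` implements an end-to-end analysis of experience-sampled hay
fever symptom diaries: mobile-app users repeatedly report three ordinal
severity scores (*nose*, *eyes*, *breathing*, each 0–3) plus a daily
medication flag, each report carrying a timestamp and a symbolic postcode
region. The pipeline labels reports urban or rural from the region's ONS
rural–urban category, compares severity and symptom duration between the
two strata, and correlates symptom series with pollutant, meteorological
and pollen measurements from a sparse sensor network, gap-filled across a
region adjacency graph.

Because real symptom diaries of this kind are not publicly distributable,
the package ships a first-class synthetic-data module that generates every
input the analysis consumes. All statistical machinery is tested against
independent oracles on small cases and against the generator, where the
injected effects are known.

## The synthetic diary generator

### Latent-Gaussian threshold model for ordinal scores

Each user $u$ has a latent baseline $b_u \sim N(\mu_b, \sigma_b^2)$. On a
reporting day $d$ the latent severity is

$$\eta_{ud} = b_u + \beta \, g(d) + \delta \, \mathbb{1}[\text{urban}(u)],$$

where $g(d) \in [0,1]$ is the min–max-scaled daily grass pollen signal,
$\beta$ (`pollen_effect`) is the seasonal driver and $\delta$
(`urban_offset`) is the latent urban shift. Each of the three symptoms
adds independent $N(0, \sigma^2)$ noise and is discretised through three
increasing cut points (`score_thresholds`) into 0–3. This is the simplest
generator that produces zero-inflated ordinal scores with a controllable
group offset; sharing $\eta_{ud}$ across the three symptoms while adding
per-symptom noise makes symptoms co-move without being identical, as
observed in real diaries. The medication flag is Bernoulli with log-odds
increasing in the day's maximum score.

Default parameters (one object, `simulation_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_users`, `date_range` | 250, 2016-03-01..09-30 | one pollen season; with `reporting_probability = 0.25` this yields ~13k reports, the scale of one year of a national citizen-science study |
| `score_thresholds` | 0.75 / 1.75 / 2.75 | with baseline $N(-0.25, 0.75^2)$ and unit noise, ~60% of scores are 0 (zero inflation) and 3s are rare |
| `urban_offset` | 0.6 | produces urban−rural `max_score` differences of ~0.4–0.5 score units, the magnitude reported for such cohorts |
| `pollen_effect` | 1.2 | grass-driven seasonality strong enough to dominate the other (causally inert) environmental variables |
| `spatial_corr` | 0.7 | pairwise inter-site correlation typical of regional-scale pollutant monitors |

Grass pollen is deliberately the *only* symptom driver: it is the single
environmental variable for which positive symptom correlations are
expected in both strata; all other variables are generated with realistic
seasonality but are causally inert unless the caller rewires the driver.

`calibrate_urban_offset()` inverts the model: given a target gap in mean
`max_score` it solves for $\delta$ by integrating
$E[\max] = \sum_k \left(1 - \Phi\!\big((t_k - \eta)/\sigma\big)^3\right)$
over the baseline distribution (181-point Gaussian grid over ±4.5 SD) and
the season's scaled pollen values, then root-finding with `uniroot` at
tolerance 1e-8. Simulation studies use it to inject a *known* group gap.

### Regions, sensors and environmental series

Regions are symbolic (no coordinates). The adjacency graph is a random
spanning tree plus ~0.3·n extra edges — sparse, connected, planar-ish;
only connectivity and ring structure matter downstream. A configurable
fraction of regions receives urban ONS codes (A1/B1/C1/C2), the rest
rural codes.

Each variable's daily signal is a shared seasonal mean (smooth annual
cosine for pollutants and meteorology; a Gaussian bell around the taxon's
flowering peak for the 12 pollen taxa, so hazel peaks in early March and
grass in mid-June) plus a mixture
$\sigma_v(\sqrt{\rho}\, z_d + \sqrt{1-\rho}\, e_{sd})$ of a shared daily
deviation and site noise, which gives pairwise inter-site correlation
$\approx \rho$ (`spatial_corr`). Pollutant/meteorology sites emit hourly
values (daily signal + shared diurnal sinusoid + small hourly noise);
pollen sites emit non-negative integer daily counts (truncation at zero
slightly attenuates pollen inter-site correlations; the generator's
correlation checks therefore use pollutant series).

What the generator does *not* emulate: atmospheric chemistry and
inter-pollutant dependence, weekday/weekend cycles, spatially structured
(rather than exchangeable) site noise, demographic confounding, and
user-level reporting-rate heterogeneity (a single `reporting_probability`
is exposed rather than guessing a distribution family). Passing tests
demonstrate that the *machinery* recovers known effects under this model,
not that real diaries satisfy the model.

## Preprocessing

Three filters, in order: (1) keep reports in the month window (default
March–September, when pollen is monitored and allergies strongest);
(2) keep only the latest report per user per calendar day (ties keep the
later input row); (3) drop users with fewer than 10 distinct retained
reporting days. The minimum-days count is evaluated *after* the month
window by default — the order the filters are naturally stated in — and
`filter_policy(min_days_before_window = TRUE)` switches to counting on
the full calendar, since the original order is not fully determined.
The filter is idempotent and leaves at most one report per user-day,
which the duration analysis relies on.

`max_score` is the maximum of the three scores. Early-cohort data without
user identifiers gets `derive_user_id()` (year-of-birth | gender |
region). Land use comes solely from the region's ONS category: A1, B1,
C1, C2 (England and Wales) and 1, 2, 3 (Scotland) are urban, everything
else rural; unknown codes fall back to rural with a warning because the
scheme enumerates the urban codes explicitly.

## Concentric-regions estimation

Hourly pollutant/meteorology series are aggregated to site-day means and
maxima, keeping a site-day only when at least 75% of its 24 hourly values
are present (`min_completeness = 0.75`) — a transparent completeness
threshold in place of hourly imputation, which is out of scope here.
Pollen counts are already daily.

To estimate a variable for a region-day with no local sensor, the search
expands in adjacency rings: ring 0 is the region itself, ring $k$ the
regions at graph distance exactly $k$. The smallest ring containing at
least one site with data supplies the estimate as the plain arithmetic
mean over those sites (no distance weighting; sites within a ring are
exchangeable). By default the search is unbounded (up to the graph
diameter), since pollen networks are sparse enough that estimates must
sometimes come from distant rings. A region's daily *maximum* is the mean
of the contributing sites' daily maxima (`max_combine = "max"` switches
to their maximum; the original cross-site combination rule is unstated).
The implementation is a hand-rolled breadth-first expansion, checked in
the tests against all-pairs shortest paths from igraph on hundreds of
random graphs.

Same-region matching (`matching = "same_region"`) restricts estimates to
`ring_used == 0` before linking, keeping a column of missing values for
variables with no in-region sensor anywhere, so both matching modes
produce identically shaped tables.

## Severity comparison

The severity comparison operates on *daily-mean distributions*: for each
land-use group the mean score per calendar day, then group mean, Cohen's
d with pooled SD, and the two-sample Kolmogorov–Smirnov distance (called
U1 in this literature, range 0–1) with the asymptotic two-sided p-value.
Raw-score comparison is available via `use_daily_means = FALSE`. The
subsample bootstrap draws 2000 subsamples of 20% of each group's reports
without replacement (the natural reading of "samples containing 20% of
the total"; with-replacement is a switch) and plots the two histograms of
subsample means; a separation that survives subsampling is not driven by
a few prolific reporters. No multiple-testing correction is applied
anywhere in the pipeline, matching the descriptive presentation it
reproduces; p-value thresholds should be read accordingly.

### A calibration caveat

The KS test treats the two samples of daily means as iid draws. With
persistent per-user baselines they are not: a finite cohort's mean
baseline differs between the urban and rural groups in every realisation
and shifts all of a group's daily means together, so the test genuinely
over-rejects under a zero urban offset — and the imbalance does not
vanish with cohort size, because the between-group offset SD and the
daily-mean SD both scale as $1/\sqrt{n_\text{users}}$. The package's
Type-I calibration study therefore uses an exchangeable null (balanced
groups, `baseline_sd = 0`), under which the measured rejection rate is
~0.03–0.05; with heterogeneous users the daily-mean KS p-values are
anti-conservative and the bootstrap check above is the more honest guard.
This is the simulation counterpart of the caution that sporadic reporting
makes within-subject inference unreliable in such cohorts.

## Symptom chains

A chain is a maximal run of calendar days whose report scores at least
`min_score`, tolerating up to `allowed_gap` consecutive days with *no
report at all*; a reported sub-threshold day always breaks the chain,
even when the gap allowance would cover it, because the gap is defined
strictly over non-reporting days. Duration is the calendar span from
first to last qualifying day inclusive, so a bridged no-report day counts
toward duration and the gap parameter is consequential; a
`report_days` variant counts only qualifying days (the original counting
rule is unstated, hence the flag). Per user the mean chain duration is
taken, per group the median of user means; users with no chain are
excluded from the median rather than contributing zeros (also a
documented choice — zeros would conflate "never symptomatic" with "short
episodes"). Useful invariants, all tested: durations are non-decreasing
and chain counts non-increasing in `allowed_gap`; qualifying days are
conserved across the segmentation; raising `min_score` shrinks the
qualifying-day set.

## Correlation analyses

All correlations are Pearson product-moment on pairwise-complete pairs
with the two-tailed t-transform p-value (the coefficient flavour is a
package choice; Spearman is available for sensitivity runs). Weekly
periods are ISO calendar weeks, months calendar months, and each
(year, period) pair is one observation. Outputs keep only rows with
p ≤ 0.05 (configurable via `alpha = 1`), ordered by significance then
|r|.

* **UK-wide** (`ukwide_correlations`): per stratum, the symptom series is
  the period mean of the stratum's daily means; the environmental series
  the period mean of the daily value averaged over the selected sites.
  Pollutant sites are restricted to urban/rural *background* types by
  default (roadside and industrial sites track local events, not regional
  patterns); `"stratified"` pairs urban reports with urban-background and
  rural reports with rural-background pollutant sensors; pollen and
  meteorology sites carry no location type and are always included except
  in stratified mode.
* **Regional** (`regional_correlations`): report-level (symptom, linked
  estimate) pairs at daily frequency; at coarser frequencies both sides
  are first averaged per (region, period) — per-report pairing is behind
  `average = "report"` since the original aggregation unit is not
  explicit. All pollutant sensor types are used at regional level.
* **Inter-sensor** (`intersensor_correlations`): within-region and
  UK-wide medians of significant pairwise site correlations per variable,
  the diagnostic for whether a sparse network can stand in for regional
  conditions at all.

## Numerical choices and degenerate inputs

* KS p-values use the asymptotic two-sample formula (`exact = FALSE`);
  daily-mean samples are large and near-continuous, and ties make the
  test mildly conservative.
* Cohen's d errors on zero pooled SD; `correlate()` errors on fewer than
  3 complete pairs or zero variance, and screening functions skip such
  combinations rather than failing.
* A missing regional estimate is a value, not an error, and propagates as
  `NA` through the link step (left join, row count preserved).
* All generator functions take explicit integer seeds and restore the
  caller's RNG state; identical config + seed gives byte-identical
  output.

## Problem sizes used in the shipped studies

The packaged simulation studies run at reduced but statistically
meaningful sizes, chosen as the package's own benchmark conditions:
parameter recovery at 200 users × 180 days × 50 seeds against a
calibrated true gap of 0.4; KS size at 100 users × 120 days × 200 seeds;
correlation-screening calibration at 60 users × 100 seeds with one site
per variable; oracle sweeps over 200 random graphs (≤30 regions) and
10,000 random score sequences. The acceptance script runs the full
default study (250 users, 21 variables, 2 sites each) once per seed.

## Known limitations

Symbolic regions only (no coordinates, no kriging or inverse-distance
weighting); no hourly imputation; no medication stratification (the flag
is an extra severity indicator only, since reports do not say whether
symptoms were recorded before or after antihistamines); no lag modelling
beyond period aggregation; and the calibration caveat above whenever
daily-mean tests are read inferentially rather than descriptively.
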