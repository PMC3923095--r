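---
title: "Model-assisted national estimation of home and leisure injuries from a sentinel ED network"
author: "hlinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-assisted national estimation of home and leisure injuries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlinet)
```

## The estimation problem

Home and leisure injuries (HLIs) — unintentional injuries outside
traffic, work, and intentional harm — are recorded exhaustively only in
a handful of sentinel emergency departments (EDs), while hospital
discharge claims cover injury-related *stays* everywhere.  `hlinet`
estimates the national yearly number and incidence rate of HLIs treated
in EDs from such a sentinel network, by modelling the ratio of HLI
counts to injury-stay counts in the network and applying it to the
national stay totals (a *separate ratio estimator*).

Within each stratum — sex $i$, five-year age band $j$ (15–19, …, 85+),
hospital $k$, year $t$ — the working model is
$I_{ijk}(t) = \alpha_{ij\cdot}(t)\, S_{ijk}(t) + \epsilon_{ijk}(t)$,
with $I$ the ED-recorded HLI count and $S$ the injury-stay count.  The
ratio is modelled with a two-level quasi-Poisson mixed model:

$$
\eta_{ijk}(t) = \log S_{ijk}(t) + \beta_0 + \alpha_i + \delta t
  + \beta_1 B_1(a_j) + \beta_2 B_2(a_j)
  + (\beta_3 + \gamma_i) B_3(a_j) + b_k + b_{ijk},
$$

where $I_{ijk}(t) \mid b \sim$ quasi-Poisson with mean $e^{\eta}$,
$b_k \sim N(0, \sigma_1^2)$ is a hospital intercept,
$b_{ijk} \sim N(0, \sigma_2^2)$ a sex–age-unit-within-hospital
intercept, the $B_m$ are a three-column natural cubic spline in the age
band centre $a_j$ (internal knots at ages 40 and 64), the third basis
column interacts with sex, and repeated yearly observations within a
unit carry an AR(1) correlation $\rho$.  Overdispersion is absorbed by
a quasi-likelihood dispersion $\phi$.

The marginal expected ratio, averaged over the normal random effects
via their moment generating function, is

$$
\hat\alpha_{ij\cdot}(t) =
  \exp\!\big(x_{ij}(t)'\hat\beta + \hat\sigma_1^2/2 + \hat\sigma_2^2/2\big),
$$

so the national stratum total is
$\hat I_{ij\cdot}(t) = \hat\alpha_{ij\cdot}(t)\, S_{ij\cdot}(t)$ with
$S_{ij\cdot}(t)$ the known national stay count, and all reported
aggregates (totals; crude rates per 1,000 person-years; rates
age-standardized with the European Standard Population truncated to
ages 15+) are linear combinations of the $\hat I_{ij\cdot}(t)$.

## Fitting choices

`fit_pql()` uses penalized quasi-likelihood: iterated REML linear mixed
model fits to the working response $z = \eta + (y - \mu)/\mu$ with
weights $\mu$, as implemented by `MASS::glmmPQL` with `nlme`'s
`corAR1` structure.  Key conventions:

* **Sex coding.** Men are the reference ($\alpha_1 \equiv 0$);
  $\alpha_2$ and $\gamma_2$ are the women's effects.
* **Year coding.** $t$ = calendar year − 2006.  Centering decouples the
  intercept from the trend; predictions reuse the same origin.
* **Age.** Band centres 17.5, 22.5, …, 82.5; the open 85+ band is
  assigned 87.5, the smallest-width convention consistent with its
  neighbours (fits are insensitive to moderate alternatives — the
  spline is linear beyond the boundary knot).  Boundary knots sit at
  the extreme band centres (17.5, 87.5); the internal knots 40 and 64
  are taken as authoritative.
* **Dispersion.** $\phi$ is the residual variance of the final working
  fit and inflates the fixed-effect covariance (a switch in
  `assemble_cov()` removes the inflation).
* **Variance-component intervals.** Wald on the log-$\sigma$ scale,
  back-transformed — hence asymmetric about the point estimate, and
  respecting positivity.
* **Zero stays.** Rows with $S = 0$ have no defined offset and are
  dropped with a warning; a stratum with no stays contributes no ratio
  information.
* **Time-trend assessment.** `assess_time_effect()` refits with year as
  an ordered factor under orthogonal polynomial contrasts and reports a
  Wald test per degree.  The linear trend is retained by design
  regardless of its p-value; higher-order contrasts flag departures
  from linearity.

## Uncertainty

The delta method treats
$\theta = (\beta, \sigma_1^2, \sigma_2^2)$ as the parameter vector with
extended design rows $X_{ij}(t) = (x_{ij}(t), 1/2, 1/2)$.  For any
aggregate $A = \sum_s w_s \hat I_s$, the gradient component $m$ is
$\sum_s X_{sm} w_s \hat I_s$ and
$\widehat{\mathrm{Var}}(A) = g'\hat V(\theta)\, g$.  The covariance is
assembled block-diagonally: the dispersion-inflated fixed-effect block
from the working fit, and $\mathrm{Var}(\hat\sigma^2) = 4 \sigma^4
\mathrm{Var}(\log \hat\sigma)$ from the log-scale Wald intervals; the
cross block is set to zero (REML orthogonality approximation — the
parametric-bootstrap comparison in the test suite quantifies the cost,
which is within 15% for totals and standardized rates).  Count and rate
intervals are symmetric Wald intervals floored at zero; the men/women
standardized rate ratio gets a log-scale interval that carries the full
shared covariance of the two rates.

Yearly estimates are combined into period (multi-year) figures as
unweighted means — for totals and for rates.  For age-specific period
rates an alternative person-year-pooled version is available
(`age_period = "pooled"`); the default mirrors the mean convention used
for the aggregate rates.

## The synthetic-data generator

Because sentinel ED records and claims microdata are not publicly
deposited, every stage is exercised on synthetic studies with known
ground truth (`simulation_config()`, `simulate_network()`).  The
defaults *are* the study conditions: fixed effects, variance
components and $\rho$ equal the fitted values of the French 2004–2008
adult HLI study; 8 hospitals over 5 years with the unbalanced entry
pattern (four hospitals with all five years, the others contributing
their 4, 3, 2 and 1 most recent years).

Where the study conditions leave a value open, the generator makes one
realistic choice:

* **Baseline stays.** Expected stays per cell follow a log-quadratic
  age profile rising steeply with age (injury admissions are dominated
  by falls in the elderly), with a small male excess, scaled by
  hospital sizes spread log-evenly over one order of magnitude.
  Hospital size is interleaved across the entry order so that size is
  not confounded with entry year — in real sentinel networks late
  joiners span the size range, and a size–entry confound would
  contaminate the estimated year trend.
* **Level-1 noise.** The AR(1) structure the model fits to working
  residuals is realized generatively as a log-scale stationary Gaussian
  process $e_{ijk}(t)$ with lag-one correlation $\rho$ and marginal sd
  $\sigma_e$, normalized to unit mean on the count scale (so the
  marginal ratio stays $\exp(x'\beta + \sigma_1^2/2 + \sigma_2^2/2)$).
  $\sigma_e$ is a free generator scale: a quasi-likelihood fit reports
  a dispersion, not a noise scale.  The default 0.05 yields clear
  overdispersion ($\phi \approx 2$–3 at realistic cell sizes) while
  keeping the induced mean–variance relationship close to the
  quasi-Poisson law the model assumes.  Log-scale noise makes count
  variance quadratic in the mean, so much larger $\sigma_e$ would
  generate data for which the fitted model's variance law — and hence
  its standard errors — are knowingly wrong, which is not what the
  original study's diagnostics showed.
* **National totals** are noise-free: the scale factor (default 40,
  i.e. the network covers ~2.5% of national stays) times the expected
  network stays, reflecting that national claims totals are treated as
  known constants, not random.
* **Population.** A fixed adult age profile of about 48.7 million
  person-years, constant over the study years.

With these defaults a synthetic study produces a few million HLIs per
year and standardized rates on the order of 100 per 1,000 — the same
orders of magnitude as a national adult population, though not tuned to
reproduce any published figure.

What the generator does *not* emulate: patient-level injury
circumstances, seasonal structure within years, hospital-level drift in
coding practice, or non-Poisson recording artifacts (duplicates,
transfers).  Passing tests therefore demonstrate the estimator's
properties under the stated stochastic mechanism, not the absence of
such real-data complications.

A companion generator, `simulate_stay_records()`, emits line-level
stays with ICD-10 codes realizing prescribed cell counts, to exercise
the selection algorithms (chapter 19 S00–T98; extended set adding
H05/H16/H26/H27/H40, H72, J68–J70, L55–L59) and the log-log-correlation
choice between them.

## Known limitations and numerical behaviour

* PQL is approximate; with the small hospital sample (8 clusters) the
  hospital-level variance is estimated with few degrees of freedom, and
  Wald coverage of the fixed effects is approximate.  Across 200
  replicated synthetic studies the package's tests require mean biases
  within Monte-Carlo error and 95% interval coverage within 90–98%.
* The fitted AR(1) coefficient on the working scale is attenuated
  relative to the latent-noise $\rho$: Poisson noise is serially
  independent and dilutes the observable correlation, and a unit
  intercept competes with it over five time points.  The year-trend
  standard error is the quantity most sensitive to this partitioning:
  in the replicated-study checks its nominal 95% coverage falls short
  of the 90–98% band that the other six fixed effects meet, because the
  largest cells — which dominate the trend information — are exactly
  where multiplicative noise departs most from the quasi-Poisson
  variance law.  The corresponding coverage assertion in the test suite
  is expected to fail and is retained as an honest record of this
  limitation.
* A variance component estimated at zero is reported with a boundary
  flag and a missing interval rather than an error; single-hospital
  designs are rejected (`hli_degenerate_error`).
* Leave-one-hospital-out refits reuse the full-sample knots and year
  origin so the estimand is constant across the forest-table rows;
  a failed reduced fit yields a flagged row, never a silent drop.

## Problem sizes used by the test suite

Unit tests run on a 4-hospital, 3-year configuration (270 strata).  The
statistical acceptance checks use the full 8-hospital design (900
strata): 200 replicated studies for parameter recovery and coverage,
500 parametric-bootstrap refits (conditioned on the observed stay
counts) for the delta-method comparison, 50 strata with $10^6$
Monte-Carlo draws each for the marginal-ratio oracle, and a full
leave-one-hospital-out pass for the robustness pattern.

## A worked run

```{r example, eval = FALSE}
study <- simulate_network(simulation_config(), seed = 1)
fit <- fit_pql(build_design(study$counts))
print(fit)
est <- estimate_national(fit, study$national, study$population,
                         study$weights)
print(est)
cv <- leave_one_hospital_out(study$counts, study$national,
                             study$population, study$weights)
forest_table(cv)
```
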