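---
title: "Methods: exposure assessment, phenotyping, and mixed models in migrenv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure assessment, phenotyping, and mixed models in migrenv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`migrenv` implements the statistical machinery of a frequency-matched
case-control study, plus a case-case severity analysis, of long-term
environmental exposures and migraine headache as captured in electronic
health records (EHR). Real patient data of this kind are protected, so the
package pairs the analysis machinery with a synthetic cohort generator whose
ground truth is known exactly; every statistical claim the package makes is
validated by parameter recovery, coverage and oracle-agreement tests against
that generator.

The pipeline has six stages:

1. **Exposure assessment** — four exposure measures per patient.
2. **Case ascertainment** — an EHR phenotyping score with case and severity
   thresholds.
3. **Frequency matching** — 3:1 control selection on four matching
   variables.
4. **Exclusions** — a three-step cascade with exact per-arm bookkeeping.
5. **Mixed models** — random-intercept logistic and negative binomial
   regressions, with penalized-spline dose-response checks.
6. **Diagnostics** — Moran's I on model residuals with a permutation null.

# Exposure model

Each patient carries four exposures, measured once (a single static epoch;
residential histories and time-varying exposure are out of scope):

* **PM2.5** (µg/m³) and **NO2** (ppb): linked verbatim from the patient's
  census block group. The pollutant surfaces are inputs, not estimated.
* **IDW methane emissions** (kg/hour·km⁻²): for patient $j$ with sources $i$
  within the buffer, $\sum_i E_i / d_{ij}^2$, where $E_i$ is the source's
  emission rate in kg/hour and $d_{ij}$ the distance in km.
* **IDW active wells** (km⁻²): $\sum_i 1 / d_{ij}^2$ over *active* wells
  within the buffer; inactive wells never contribute.

Two binary forms (any emitter within 10 km; any active well within 10 km)
support the secondary analyses, and the methane sum decomposes by source
category (dairy/landfill versus other industrial) for the sensitivity
analysis.

Numerical choices, all configurable:

* **Buffer**: 10 km, *closed* — a source at exactly 10 km counts. The
  boundary behavior is not dictated by the formula, so the package fixes
  and documents one convention.
* **Distance floor**: distances are floored at 0.05 km before squaring. The
  inverse-square kernel diverges as $d \to 0$; without a floor a co-located
  source dominates every other term. 50 m is roughly parcel scale.
* **Metric**: great-circle (haversine, Earth radius 6371 km) on geographic
  coordinates. At a study-region scale (a few hundred km), projection
  differences are far below the kernel's own sensitivity to the floor; a
  planar option exists for synthetic grids and for exact-arithmetic tests.
* **Rescaling**: model coefficients are reported per 5 µg/m³ (PM2.5), per
  5 ppb (NO2), per 100,000 kg/hour (IDW methane) and per 1000 IDW units
  (wells), so the continuous columns are divided by those constants before
  fitting.

# Case ascertainment

Case status comes from a migraine probability score built from three EHR
component classes: migraine-coded encounters (ICD-9 prefix `346`, ICD-10
prefix `G43`, in inpatient, outpatient or emergency settings), a
significant-health-problem-list migraine entry, and fills of
migraine-specific abortive medications (triptans, ergotamines). The score
ranges 0–101; a score above 10 defines a case and a score above 100 defines
the more-severe stratum.

The published weight table behind this score is proprietary and not
reproduced here. The package ships a **surrogate configuration** with the
same structure and thresholds:

$$\text{score} = \min(101,\; 20\,\min(n_{enc},5) + 11\,[\text{problem list}]
  + 15\,\min(n_{rx},3))$$

Every weight, cap and threshold is a configuration entry, so a site holding
the real weight table can drop it in without touching any other module. The
surrogate preserves the properties the rest of the pipeline relies on: the
0–101 range, monotonicity in migraine-coded activity, and both thresholds.
Whether encounter settings deserve different weights is unknown to us; the
config exposes the structure but the default does not guess.

Severity among cases uses five outcomes: all-cause neurology visits,
migraine-specific urgent-care visits and abortive fills (counts per
person-year, analyzed with a log person-years offset), at least one
migraine-specific emergency department (ED) visit during the window, and
score > 100. Person-years are taken directly from the patient record
(entry to end of window); the EHR denominator construction is not specified
upstream, so the generator exposes person-years as a first-class field
rather than deriving them from events.

# Matching and exclusions

Controls are frequency-matched 3:1 within joint strata of age category
(18–29, 30–44, 45–54, 55–64, 65+), sex, entry year, and primary-care
follow-up category (0–6, 7–24, >24 months), sampled uniformly without
replacement under a fixed seed. Strata with too few candidates keep all of
them and the shortfall is reported; strata are never relaxed or collapsed,
which keeps the design transparent at the cost of occasionally missing the
target ratio.

The exclusion cascade runs *after* matching (the order implied by the
published cohort counts): (1) residence outside the study counties,
(2) missing block-group poverty linkage, (3) missing PM2.5. A record
failing several filters is counted at the first, and the report's
arithmetic (final = initial − Σ removed, per arm) is checked exactly in the
tests.

# Mixed models

All primary models are single-random-intercept GLMMs with county as the
grouping factor: logistic for case status and the two severity dichotomies,
NB2 negative binomial (variance $\mu + \alpha\mu^2$) with a log
person-years offset for the three severity counts. The adjustment set is
age category, sex, race/ethnicity, Medicaid use, primary-care visits per
person-year, block-group population density and percent poverty; the BMI
category, marital status, and distance-to-ED terms appear only in the
sensitivity re-runs. Categorical covariates are reference-coded against the
first level in lexicographic order. Population density enters as
individuals per 1000/km² so that all design columns are unit scale.

**Estimation** is by maximizing the marginal likelihood with the random
intercept integrated out by adaptive Gauss–Hermite quadrature (default 15
nodes): each county's integrand is recentred at its conditional mode and
rescaled by the mode curvature, both found by a damped Newton iteration
(the integrand is strictly log-concave for both families, so the mode is
unique). This estimator was chosen over penalized quasi-likelihood because
it is directly checkable: the tests compare the quadrature
log-likelihood against a dense (10,000-point) numerical integration oracle
to 1e-6 relative error, and fixing $\sigma_u = 0$ must and does reproduce
ordinary GLM coefficients. The NB2 dispersion is estimated jointly on the
log scale. The optimizer runs a quasi-Newton pass with forward-difference
gradients and then polishes with central differences; standard errors come
from the inverse of the numerically differentiated observed information,
giving Wald intervals (symmetric on the log scale; profile likelihood is
out of scope). The convergence flag is honest: optimizer success, a
positive-definite information matrix, and no coefficient shifting the
linear predictor by more than 12 per standard deviation of its column (a
scale-invariant separation heuristic). Failed fits are flagged and kept in
the output grid, never silently dropped or refitted.

**Dose-response checks** refit each continuous exposure as a cubic P-spline
(8 basis functions, second-difference penalty) in a generalized additive
mixed model with the county intercept as a random-effect smooth, via
`mgcv::gam`. The smoothing parameter is chosen by marginal likelihood
(`method = "ML"`). The upstream description of the spline machinery names
no implementation or smoothing criterion; delegating to `mgcv` (rather than
hand-rolling a P-IRLS loop with a grid search) buys a battle-tested
penalized-likelihood optimizer whose `sp → ∞` limit demonstrably reproduces
the linear fit, which is the property the tests need. The reported
nonlinearity summary is the effective degrees of freedom of the exposure
smooth, a linear-versus-spline deviance comparison, and a monotonicity
check of the fitted curve on a grid.

# Spatial diagnostics

Residual spatial autocorrelation is assessed with Moran's I on deviance
residuals (computed at the conditional fit, with empirical-Bayes county
intercepts plugged in), using row-standardized k-nearest-neighbor weights
(k = 8) on residence coordinates — the upstream analysis does not state its
weight matrix or residual type, so the package fixes and documents this
choice. Significance comes from ≥ 999 random permutations of the residuals
across locations (null expectation −1/(n−1)). The diagnostic is
reporting-only: the pipeline never auto-corrects a model based on it. Above
1500 observations a seeded subsample bounds the O(n²) distance work.

# The synthetic world

The generator is first-class, tested code; its defaults are the stated
world the validation suite runs in.

* **Geography**: counties uniform in a Northern-California-sized bounding
  box; block groups cluster around county centers (SD ≈ 15 km). Pollutant
  surfaces are a low-order trend plus smooth Gaussian bumps, min–max
  rescaled into the observed ranges (PM2.5 3.7–13.3 µg/m³, NO2 1.1–15.2
  ppb), which makes neighboring block groups correlated by construction.
  Poverty is Beta-distributed (median ≈ 7%), density lognormal
  (median ≈ 2250 /km²), both matching the published cohort medians.
* **Sources**: 60 methane super-emitters (35:25 dairy-landfill:other
  split), lognormal emission rates (median 2000 kg/hour, heavy tail), with
  30% of emitters anchored near populated block groups; 2000 wells in 6
  spatial fields anchored *near* but offset from towns, 85% active. These
  placements reproduce the qualitative exposure distribution of the real
  cohort: roughly a fifth of residences within 10 km of an emitter, an
  order-of-magnitude smaller fraction near wells, and heavy-tailed IDW
  sums driven by rare close encounters.
* **Patients**: residences are block-group centroids plus isotropic 500 m
  jitter (preserving block-group linkage while keeping IDW distances
  nondegenerate); demographics follow the published control-arm marginals
  and are configurable; follow-up categories map to person-years drawn
  uniformly within each band.
* **Outcomes**: latent case status is Bernoulli with logit = intercept +
  Σ β·(rescaled exposure) + county random intercept (SD `county_sigma`,
  default 0.3). The default intercept puts the population case rate near
  15%, leaving enough candidates for 3:1 matching. Severity counts are NB2
  draws with a log person-years offset and county intercepts; the ED-visit
  and severe-score dichotomies are logistic draws.
* **Events**: cases receive migraine-coded encounters, problem-list flags
  and fills *constructed to score consistently with their latent status*
  under the default surrogate configuration — non-severe cases draw 1–2
  scoring encounters (maximum attainable score 96), severe cases draw 5
  encounters plus the problem-list flag (minimum 111, capped at 101), and
  non-cases receive no migraine-coded activity (score 0). The scoring
  round trip is therefore exact by design, and the tests verify 100%
  agreement. One scoring encounter moves to the ED setting when an ED
  visit was drawn, so the severity outcome and the score share events the
  way they would in a real record.

What a green test does *not* establish: the generator's event streams are
far simpler than real EHR data (two diagnosis-code families, no coding
noise, no migration, no informative missingness, no correlation between
demographics and exposure beyond geography). Green tests establish that
the *machinery* is correct — that the estimators recover the parameters of
the model they assume, at the stated sizes — not that the published
effect estimates are reproducible, which protected data make impossible.

# Acceptance checks

`tests/testthat/test-acceptance.R` implements eight checks: the exclusion
cascade and published-percentage arithmetic (exact); IDW brute-force oracle
agreement (1e-10, 100 random fields); the 2×2 cross-product OR and the
dense-integration quadrature oracle (1e-6); parameter recovery at
n = 20,000 plus CI coverage (95% ± 4%) and type-I error (5% ± 3%) over 200
cohorts of n = 2,000; spline discrimination between linear and inverse-U
truths; and Moran oracle agreement (1e-12) with the permutation-null
expectation. The specification attached no numeric acceptance targets
(the study's headline estimates are not reproducible from synthetic data),
so `scripts/acceptance.R` emits an empty JSON object after exercising the
installed package end to end.

# Known limitations

* One random-intercept level only; no crossed or nested random effects.
* Wald inference only; no profile-likelihood or bootstrap intervals.
* The score weight table is a documented surrogate, not the proprietary
  original.
* Static exposure; no residential mobility or time-varying sources.
* The permutation Moran test treats residuals as exchangeable, which is
  approximate once covariates induce heteroscedasticity.
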