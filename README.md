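# migrenv

Case-control and case-case analysis machinery for studying **long-term
environmental exposures and migraine headache** in electronic health record
(EHR) cohorts — with a synthetic cohort generator (known ground truth) that
validates every statistical component.

## Who this is for

Environmental epidemiologists and biostatisticians who need the full chain
of such a study as tested, reusable code: point-source exposure assessment,
EHR phenotyping, frequency matching, mixed-model estimation, dose-response
checks, and spatial residual diagnostics. Real migraine EHR extracts are
protected health information; this package runs end to end on synthetic
data so the methodology is reproducible even where the data are not.

## What it computes

**Exposures** (per patient, single epoch):

- Block-group PM2.5 (µg/m³) and NO2 (ppb), linked verbatim.
- Inverse-distance-weighted methane emissions from point sources within a
  closed 10 km buffer: `sum_i E_i / d_ij^2` (kg/hour, km), with a 0.05 km
  distance floor.
- Inverse-distance-weighted active oil/gas wells: `sum_i 1 / d_ij^2`.
- Binary indicators: any emitter / any active well within 10 km.

Coefficients are reported per 5 µg/m³ (PM2.5), per 5 ppb (NO2), per
100,000 kg/hour (IDW methane) and per 1000 IDW units (wells).

**Phenotype**: a migraine probability score in [0, 101] built from
migraine-coded encounters (ICD-9 `346.*` / ICD-10 `G43.*`), a problem-list
flag, and abortive-medication fills; score > 10 defines a case, > 100 the
severe stratum. The component weights are a documented, configurable
surrogate (the original table is proprietary). Severity outcomes among
cases: neurology visits, migraine urgent-care visits and triptan fills per
person-year, any migraine ED visit, and score > 100.

**Models**: random-intercept (county) logistic and NB2 negative binomial
GLMMs fitted by **adaptive Gauss–Hermite quadrature** (15 nodes by
default, verified to 1e-6 against dense numerical integration), with log
person-years offsets for count outcomes, Wald CIs from the observed
information, penalized-spline (`mgcv`) dose-response checks, and Moran's I
permutation diagnostics on deviance residuals.

## Worked example

```r
library(migrenv)

region  <- generate_region(n_counties = 8, n_block_groups = 80, seed = 1)
sources <- generate_sources(region, seed = 2)
truth   <- true_model(exposure_betas = c(no2 = log(1.5)),
                      county_sigma = 0.3, seed = 3)
cohort  <- generate_cohort(region, sources, n_patients = 4000, truth)

asc  <- ascertain_cohort(cohort$patients, cohort$events)
expo <- rescale_exposures(compute_exposures(cohort$patients, region, sources))
d    <- merge(merge(cohort$patients, expo, by = "patient_id"),
              asc[, c("patient_id", "is_case")], by = "patient_id")

fit <- fit_glmm(model_spec("is_case", "no2", "logistic",
                           covariates = c("age_cat", "sex"),
                           scale_label = "per 5 ppb"), d)
fit
#> Random-intercept logistic model: is_case ~ no2 (+2 covariates)
#> n = 4000, groups = 8, sigma_u = 0.3193, loglik = -2273.68, converged
#> OR = 1.4737 (95% CI 1.1211, 1.9372) per 5 ppb

moran_diagnostic(fit, d, n_perm = 199, seed = 4)
#> Moran's I = 0.0124 (E[I] = -0.0007), p_perm = 0.2200 (199 perms, knn8_row_standardized)
```

The fitted odds ratio (1.47 per 5 ppb NO2) recovers the generator's true
effect (1.5) within its confidence interval; the Moran diagnostic shows no
residual spatial autocorrelation, as expected when the fitted model matches
the data-generating model. `run_study(study_config(...))` runs the whole
pipeline — ascertainment, 3:1 frequency matching, the exclusion cascade,
the case-control grid (4 continuous + 2 binary exposures + 4 spline
checks), the case-case grid (4 exposures × 5 severity outcomes, plus
binary-exposure secondary models), three sensitivity analyses, and
per-model Moran diagnostics — and returns labeled effect tables.

A command-line wrapper with `synth` / `ascertain` / `match` / `exposures` /
`fit` / `diagnose` / `run-all` subcommands is installed at
`system.file("cli", "migrenv-cli.R", package = "migrenv")`.

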