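#' Ground-truth parameters for the synthetic cohort generator
#'
#' The generator draws latent migraine case status from a logistic model with
#' county random intercepts and the four rescaled exposures, then (for cases)
#' draws severity counts from NB2 negative binomial models with a log
#' person-years offset and dichotomous severity flags from logistic models.
#' The returned object is the single source of truth for parameter-recovery
#' tests.
#'
#' @param intercept Log-odds of case status at zero exposure for an average
#'   county. Default `qlogis(0.15)`: a population case rate around 15%,
#'   leaving enough non-cases for 3:1 frequency matching.
#' @param exposure_betas Named log-OR per *rescaled* exposure unit; names
#'   among `pm25`, `no2`, `methane_idw`, `well_idw`,
#'   `any_emitter_10km`, `any_well_10km`. Default all zero.
#' @param covariate_betas Named numeric of covariate log-ORs. A name of the
#'   form `"col"` multiplies a numeric patient column; `"col=level"` is an
#'   indicator for a factor level (e.g. `"sex=female"`). Default none.
#' @param county_sigma SD of the county random intercepts (>= 0).
#' @param severity List with `dispersion` (NB2 alpha > 0), `exposure_betas`
#'   (named log-RR per rescaled unit applied to every severity outcome) and
#'   intercepts `neurology`, `urgent_care`, `triptan` (log rate per
#'   person-year), `ed`, `severe` (log-odds). Defaults match the observed
#'   cohort-level rates (1.2 neurology visits/py, 0.2 urgent-care/py, 0.6
#'   triptans/py, 4.5% with an ED visit, 33.5% severe).
#' @param seed Integer seed governing all generator randomness.
#' @return Object of class `true_model`.
#' @export
true_model <- function(intercept = stats::qlogis(0.15),
                       exposure_betas = c(pm25 = 0, no2 = 0,
                                          methane_idw = 0, well_idw = 0),
                       covariate_betas = numeric(0),
                       county_sigma = 0.3,
                       severity = list(),
                       seed = 1) {
  sev <- utils::modifyList(list(
    dispersion = 1,
    exposure_betas = c(pm25 = 0, no2 = 0, methane_idw = 0, well_idw = 0),
    neurology = log(1.2), urgent_care = log(0.2), triptan = log(0.6),
    ed = stats::qlogis(0.045), severe = stats::qlogis(0.335)
  ), as.list(severity))
  # JSON configs deliver named lists; flatten to named numerics
  sev$exposure_betas <- unlist(sev$exposure_betas)
  exposure_betas <- unlist(exposure_betas)
  covariate_betas <- unlist(covariate_betas)
  if (is.null(exposure_betas)) exposure_betas <- numeric(0)
  if (is.null(covariate_betas)) covariate_betas <- numeric(0)
  stopifnot(is.finite(intercept), all(is.finite(exposure_betas)),
            county_sigma >= 0, sev$dispersion > 0)
  structure(list(intercept = intercept,
                 exposure_betas = exposure_betas,
                 covariate_betas = covariate_betas,
                 county_sigma = county_sigma,
                 severity = sev,
                 seed = seed),
            class = "true_model")
}

#' Default demographic marginals
#'
#' Sampling probabilities for the categorical patient covariates. The
#' defaults follow the control-arm marginals of the study population:
#' 82.5% female; age bands 18.9/36.9/21.5/14.1/8.7%; race/ethnicity
#' 19.9% non-Hispanic Asian, 3.8% Black, 48.2% white, 15.5% other, 12.6%
#' Hispanic; 5.6% Medicaid; and the published marital and BMI category
#' distributions.
#'
#' @return Named list of probability vectors.
#' @export
default_demographics <- function() {
  list(
    age_cat = c("18-29" = 0.189, "30-44" = 0.369, "45-54" = 0.215,
                "55-64" = 0.141, "65+" = 0.087),
    sex = c(female = 0.825, male = 0.175),
    race_ethnicity = c(nh_asian = 0.199, nh_black = 0.038, nh_white = 0.482,
                       nh_other = 0.155, hispanic = 0.126),
    medicaid = c(yes = 0.056, no = 0.944),
    marital = c(div_sep_wid = 0.070, married = 0.575, single = 0.236,
                other_unknown = 0.119),
    bmi_cat = c(underweight = 0.020, normal = 0.414, overweight = 0.293,
                obese1 = 0.146, obese2 = 0.064, obese3 = 0.043,
                missing = 0.020),
    entry_year = c("2014" = 0.2, "2015" = 0.2, "2016" = 0.2, "2017" = 0.2,
                   "2018" = 0.2),
    followup_cat = c("0-6m" = 0.15, "7-24m" = 0.25, ">24m" = 0.60)
  )
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# Evaluate named covariate effects against the patient frame.
# "col" -> beta * numeric column; "col=level" -> beta * indicator.
covariate_effect <- function(patients, betas) {
  eff <- numeric(nrow(patients))
  for (nm in names(betas)) {
    parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
    col <- parts[1]
    if (!col %in% names(patients)) stop("unknown covariate in truth: ", col)
    x <- if (length(parts) == 2) as.numeric(patients[[col]] == parts[2])
         else as.numeric(patients[[col]])
    eff <- eff + betas[[nm]] * x
  }
  eff
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Patients live at jittered block-group centroids (isotropic jitter, default
#' SD 500 m), carry demographics drawn from configurable marginals, an entry
#' year, a follow-up category with matching person-years, and a latent case
#' status drawn from the logistic ground-truth model applied to their
#' *computed* exposures. Cases receive migraine-coded events and fills that
#' score above the case threshold under the default scoring configuration
#' and severity events from the ground-truth severity models; non-cases
#' receive no migraine-related events (score 0).
#'
#' @param region A `region` object (must be non-empty).
#' @param sources A `source_set`; an empty set is allowed, in which case the
#'   exposure model falls back to the pollutant surfaces only.
#' @param n_patients Number of patients (>= 1).
#' @param truth A `true_model`.
#' @param events If `FALSE`, skip EHR event generation (fast path for
#'   simulation studies that fit on the latent status directly).
#' @param demographics Marginals, see [default_demographics()].
#' @param jitter_km Residence jitter SD in km (default 0.5).
#' @param radius_km,floor_km IDW parameters used when computing the latent
#'   model's exposures.
#' @param p_outside Fraction of patients whose residence is relabeled to an
#'   out-of-region county (`county_id = "OUT"`), to exercise the exclusion
#'   cascade. Default 0.
#' @param p_missing_poverty,p_missing_pm25 Fractions of patients flagged as
#'   missing the block-group linkage for poverty / PM2.5. Default 0.
#' @return List with data frames `patients` and `events`, plus `county_re`
#'   (the realized county random intercepts) and the `truth` object.
#' @export
generate_cohort <- function(region, sources, n_patients, truth,
                            events = TRUE,
                            demographics = default_demographics(),
                            jitter_km = 0.5, radius_km = 10, floor_km = 0.05,
                            p_outside = 0, p_missing_poverty = 0,
                            p_missing_pm25 = 0) {
  stopifnot(inherits(region, "region"), inherits(truth, "true_model"))
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (nrow(region$block_groups) == 0) stop("region has no block groups")
  rng <- local_seed(truth$seed)
  dm <- demographics
  bg <- region$block_groups

  # residence: block group weighted by population density, jittered centroid
  bgi <- sample.int(nrow(bg), n_patients, replace = TRUE,
                    prob = bg$pop_density)
  lat <- bg$lat[bgi] + stats::rnorm(n_patients, 0, jitter_km / 111.19)
  lon <- bg$lon[bgi] + stats::rnorm(n_patients, 0, jitter_km /
                                      (111.19 * cos(bg$lat[bgi] * pi / 180)))
  followup <- sample_cat(n_patients, dm$followup_cat)
  py <- numeric(n_patients)
  py[followup == "0-6m"] <- stats::runif(sum(followup == "0-6m"), 1, 6) / 12
  py[followup == "7-24m"] <- stats::runif(sum(followup == "7-24m"), 7, 24) / 12
  py[followup == ">24m"] <- stats::runif(sum(followup == ">24m"), 24, 60) / 12

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n_patients)),
    bg_id = bg$bg_id[bgi],
    county_id = bg$county_id[bgi],
    lat = lat, lon = lon,
    age_cat = sample_cat(n_patients, dm$age_cat),
    sex = sample_cat(n_patients, dm$sex),
    race_ethnicity = sample_cat(n_patients, dm$race_ethnicity),
    medicaid = sample_cat(n_patients, dm$medicaid) == "yes",
    marital = sample_cat(n_patients, dm$marital),
    bmi_cat = sample_cat(n_patients, dm$bmi_cat),
    entry_year = as.integer(sample_cat(n_patients, dm$entry_year)),
    followup_cat = followup,
    person_years = py,
    pcp_per_py = stats::rgamma(n_patients, shape = 2, scale = 1.2),
    stringsAsFactors = FALSE
  )

  # exposures at the true residence, rescaled as in the analysis models
  expo <- compute_exposures(patients, region, sources,
                            radius_km = radius_km, floor_km = floor_km)
  expo_r <- rescale_exposures(expo)

  counties <- region$counties$county_id
  county_re <- stats::rnorm(length(counties), 0, truth$county_sigma)
  names(county_re) <- counties

  eta <- truth$intercept + county_re[patients$county_id]
  for (nm in names(truth$exposure_betas)) {
    x <- if (nm %in% names(expo_r)) as.numeric(expo_r[[nm]]) else
      stop("unknown exposure in truth: ", nm)
    eta <- eta + truth$exposure_betas[[nm]] * x
  }
  if (length(truth$covariate_betas))
    eta <- eta + covariate_effect(patients, truth$covariate_betas)
  latent_case <- stats::runif(n_patients) < stats::plogis(eta)

  # severity draws (cases only)
  sev <- truth$severity
  sev_eta <- numeric(n_patients)
  for (nm in names(sev$exposure_betas)) {
    sev_eta <- sev_eta + sev$exposure_betas[[nm]] * as.numeric(expo_r[[nm]])
  }
  size <- 1 / sev$dispersion
  draw_nb <- function(log_rate) {
    mu <- exp(log_rate + sev_eta + log(py) + county_re[patients$county_id])
    stats::rnbinom(n_patients, size = size, mu = mu)
  }
  n_neuro <- draw_nb(sev$neurology)
  n_uc <- draw_nb(sev$urgent_care)
  n_rx <- draw_nb(sev$triptan)
  ed_flag <- stats::runif(n_patients) <
    stats::plogis(sev$ed + sev_eta + county_re[patients$county_id])
  severe_flag <- stats::runif(n_patients) <
    stats::plogis(sev$severe + sev_eta + county_re[patients$county_id])

  patients$latent_case <- latent_case
  patients$latent_severe <- latent_case & severe_flag
  patients$missing_poverty <- stats::runif(n_patients) < p_missing_poverty
  patients$missing_pm25 <- stats::runif(n_patients) < p_missing_pm25
  if (p_outside > 0) {
    out_idx <- stats::runif(n_patients) < p_outside
    patients$county_id[out_idx] <- "OUT"
  }

  ev <- NULL
  if (events) {
    ev <- build_events(patients, latent_case, patients$latent_severe,
                       n_neuro, n_uc, n_rx, ed_flag)
  }
  list(patients = patients, events = ev, county_re = county_re, truth = truth)
}

# Construct per-patient event streams consistent with latent status under
# the default scoring configuration:
#   non-severe case: 1-2 migraine-coded encounters (one in the ED when an ED
#     visit was drawn), optional problem-list flag, any number of fills
#     -> score in [20, 96];
#   severe case: 5 encounters + problem-list flag -> score >= 111 -> 101;
#   non-case: no migraine-related events -> score 0.
# Fully vectorized: one concatenated frame per event family.
build_events <- function(patients, case, severe, n_neuro, n_uc, n_rx,
                         ed_flag) {
  n <- nrow(patients)
  pid <- patients$patient_id
  mig_codes <- c("G43.909", "G43.109", "346.90")

  n_enc <- integer(n)
  n_enc[case & severe] <- 5L
  n_nonsev <- sum(case & !severe)
  n_enc[case & !severe] <- sample(1:2, n_nonsev, replace = TRUE)
  # migraine-coded scoring encounters; first is in the ED when flagged
  enc <- NULL
  if (any(n_enc > 0)) {
    keep <- n_enc > 0
    reps <- n_enc[keep]
    within_seq <- sequence(reps)
    who <- rep(which(keep), reps)
    enc <- data.frame(
      patient_id = pid[who],
      event_type = "encounter",
      code = sample(mig_codes, sum(reps), replace = TRUE),
      care_setting = ifelse(within_seq == 1 & ed_flag[who], "ed", "outpatient"),
      medication_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  shp_flag <- (case & severe) |
    (case & !severe & stats::runif(n) < 0.3)
  shp <- if (any(shp_flag)) data.frame(
    patient_id = pid[shp_flag], event_type = "problem_list",
    code = "G43.909", care_setting = NA_character_,
    medication_class = NA_character_, stringsAsFactors = FALSE) else NULL
  expand <- function(counts, event_type, code_v, setting, medclass) {
    counts <- ifelse(case, counts, 0L)
    keep <- counts > 0
    if (!any(keep)) return(NULL)
    reps <- counts[keep]
    data.frame(patient_id = rep(pid[keep], reps), event_type = event_type,
               code = code_v, care_setting = setting,
               medication_class = medclass, stringsAsFactors = FALSE)
  }
  fills <- expand(n_rx, "prescription", NA_character_, NA_character_, "triptan")
  uc <- expand(n_uc, "encounter", "G43.909", "urgent_care", NA_character_)
  neuro <- expand(n_neuro, "encounter", "R51", "neurology", NA_character_)
  n_other <- ifelse(case, 0L, stats::rpois(n, 0.3))
  other <- NULL
  if (any(n_other > 0)) {
    keep <- n_other > 0
    other <- data.frame(patient_id = rep(pid[keep], n_other[keep]),
                        event_type = "encounter", code = "Z00.00",
                        care_setting = "outpatient",
                        medication_class = NA_character_,
                        stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, Filter(Negate(is.null),
                              list(enc, shp, fills, uc, neuro, other)))
  if (is.null(ev)) {
    ev <- data.frame(patient_id = character(), event_type = character(),
                     code = character(), care_setting = character(),
                     medication_class = character(), stringsAsFactors = FALSE)
    ev$date <- character()
  } else {
    ev$date <- format(as.Date("2014-01-01") +
                        sample.int(1826, nrow(ev), replace = TRUE) - 1)
    ev <- ev[order(ev$patient_id, ev$date), ]
  }
  rownames(ev) <- NULL
  ev
}

#' Write the synthetic study to delimited files
#'
#' Emits the five study tables (patients, events, sources, wells, block
#' groups) as comma-separated UTF-8 files with a header row, plus
#' `truth.json` recording the ground-truth parameters and realized county
#' random intercepts.
#'
#' @param cohort Output of [generate_cohort()].
#' @param region The `region` used.
#' @param sources The `source_set` used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_study_files <- function(cohort, region, sources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    events = file.path(dir, "events.csv"),
    sources = file.path(dir, "sources.csv"),
    wells = file.path(dir, "wells.csv"),
    block_groups = file.path(dir, "block_groups.csv"),
    counties = file.path(dir, "counties.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(cohort$events, paths["events"], row.names = FALSE)
  utils::write.csv(sources$emitters, paths["sources"], row.names = FALSE)
  utils::write.csv(sources$wells, paths["wells"], row.names = FALSE)
  utils::write.csv(region$block_groups, paths["block_groups"], row.names = FALSE)
  utils::write.csv(region$counties, paths["counties"], row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(intercept = truth$intercept,
         exposure_betas = as.list(truth$exposure_betas),
         covariate_betas = as.list(truth$covariate_betas),
         county_sigma = truth$county_sigma,
         severity = truth$severity,
         seed = truth$seed,
         county_re = as.list(cohort$county_re)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read study tables back from a directory
#'
#' Inverse of [write_study_files()] for the tabular pieces.
#'
#' @param dir Directory containing the delimited study files.
#' @return List with `patients`, `events`, `region` and `sources` objects.
#' @export
read_study_files <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  region <- structure(list(counties = rd("counties.csv"),
                           block_groups = rd("block_groups.csv")),
                      class = "region")
  sources <- source_set(rd("sources.csv"), rd("wells.csv"))
  list(patients = rd("patients.csv"), events = rd("events.csv"),
       region = region, sources = sources)
}
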