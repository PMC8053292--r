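#' Exclusion-cascade bookkeeping
#'
#' Builds the per-arm exclusion report for the three-step cascade
#' (outside-county residence, missing block-group poverty, missing PM2.5).
#' Arithmetic is exact: final = initial - sum(removed), separately per arm.
#'
#' @param initial_cases,initial_controls Counts before exclusions.
#' @param removed_cases,removed_controls Numeric vectors of per-step removal
#'   counts (same length and order for both arms).
#' @param steps Step labels.
#' @return Object of class `exclusion_report`: data frame `steps` plus
#'   `initial_cases`, `final_cases`, `initial_controls`, `final_controls`.
#' @export
exclusion_report <- function(initial_cases, removed_cases,
                             initial_controls, removed_controls,
                             steps = c("outside_county", "missing_poverty",
                                       "missing_pm25")) {
  stopifnot(length(removed_cases) == length(steps),
            length(removed_controls) == length(steps))
  if (any(removed_cases < 0) || any(removed_controls < 0))
    stop("removal counts must be nonnegative")
  final_cases <- initial_cases - sum(removed_cases)
  final_controls <- initial_controls - sum(removed_controls)
  if (final_cases < 0 || final_controls < 0)
    stop("removals exceed the initial count")
  structure(list(
    steps = data.frame(step = steps, removed_cases = removed_cases,
                       removed_controls = removed_controls,
                       stringsAsFactors = FALSE),
    initial_cases = initial_cases, final_cases = final_cases,
    initial_controls = initial_controls, final_controls = final_controls
  ), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusions: cases %d -> %d, controls %d -> %d\n",
              x$initial_cases, x$final_cases,
              x$initial_controls, x$final_controls))
  print(x$steps)
  invisible(x)
}

#' Apply the study exclusion cascade to a matched cohort
#'
#' Filters, in the fixed order (1) residence outside the study counties,
#' (2) missing block-group poverty, (3) missing PM2.5. A record failing
#' several filters is counted at the first.
#'
#' @param data Analysis data frame with columns `is_case`, `county_id`,
#'   `poverty_pct`, `pm25`.
#' @param county_filter Character vector of admissible county ids (default:
#'   all counties present that are not `"OUT"`).
#' @return List: `data` (filtered frame) and `report` (an
#'   [exclusion_report()]).
#' @export
apply_exclusions <- function(data, county_filter = NULL) {
  stopifnot(all(c("is_case", "county_id", "poverty_pct", "pm25") %in%
                  names(data)))
  if (is.null(county_filter))
    county_filter <- setdiff(unique(data$county_id), "OUT")
  f1 <- !(data$county_id %in% county_filter)
  f2 <- !f1 & is.na(data$poverty_pct)
  f3 <- !f1 & !f2 & is.na(data$pm25)
  arm <- data$is_case
  rep_ <- exclusion_report(
    initial_cases = sum(arm),
    removed_cases = c(sum(f1 & arm), sum(f2 & arm), sum(f3 & arm)),
    initial_controls = sum(!arm),
    removed_controls = c(sum(f1 & !arm), sum(f2 & !arm), sum(f3 & !arm)))
  list(data = data[!(f1 | f2 | f3), , drop = FALSE], report = rep_)
}

#' Percentage helpers for published summary counts
#'
#' `count_percent()` is the one-decimal percentage convention used in the
#' cohort description tables; `coverage_fraction()` is the same convention
#' for the fraction of surveyed point sources located near participants.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
count_percent <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be positive")
  round(100 * numerator / denominator, digits)
}

#' @rdname count_percent
#' @param n_within Sources within the buffer of any participant.
#' @param n_total Total surveyed sources.
#' @export
coverage_fraction <- function(n_within, n_total, digits = 1) {
  count_percent(n_within, n_total, digits)
}

std_covariates <- c("age_cat", "sex", "race_ethnicity", "medicaid",
                    "pcp_per_py", "pop_density_k", "poverty_pct")

exposure_scales <- c(pm25 = "per 5 ug/m3", no2 = "per 5 ppb",
                     methane_idw = "per 100,000 kg/hour IDW",
                     well_idw = "per 1000-unit IDW",
                     any_emitter_10km = "any emitter within 10 km",
                     any_well_10km = "any active well within 10 km")

#' Default study configuration
#'
#' All knobs of the synthetic end-to-end study in one list: generator sizes
#' and ground truth, IDW parameters, matching, model grid and sensitivity
#' toggles. Override any entry through `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_counties = 10, n_block_groups = 120, n_patients = 4000,
    n_emitters = 60, n_wells = 2000,
    radius_km = 10, floor_km = 0.05,
    rescale = c(pm25 = 5, no2 = 5, methane_idw = 1e5, well_idw = 1e3),
    match_ratio = 3,
    nAGQ = 15,
    truth = list(),           # overrides passed to true_model()
    p_outside = 0, p_missing_poverty = 0, p_missing_pm25 = 0,
    sensitivity = list(category_split = TRUE, bmi_marital = TRUE,
                       distance_to_ed = TRUE),
    case_control_exposures = c("pm25", "no2", "methane_idw", "well_idw",
                               "any_emitter_10km", "any_well_10km"),
    run_splines = TRUE,
    run_case_case = TRUE,
    run_case_case_binary = TRUE,
    moran_n_perm = 199, moran_max_n = 1000
  )
  utils::modifyList(cfg, list(...))
}

#' Read a study configuration from a JSON file
#'
#' @param path Path to a JSON object of configuration overrides.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, raw)
}

# Build the merged analysis table: patients + ascertainment + rescaled
# exposures, with the density covariate expressed per 1000/km^2 so the
# optimizer sees unit-scale columns.
prepare_analysis_data <- function(patients, ascertainment, region, sources,
                                  cfg) {
  expo <- compute_exposures(patients, region, sources,
                            radius_km = cfg$radius_km,
                            floor_km = cfg$floor_km)
  expo_r <- rescale_exposures(expo, cfg$rescale)
  d <- merge(patients, expo_r, by = "patient_id")
  d <- merge(d, ascertainment[, setdiff(names(ascertainment), "person_years")],
             by = "patient_id")
  if ("missing_poverty" %in% names(d))
    d$poverty_pct[d$missing_poverty] <- NA
  if ("missing_pm25" %in% names(d))
    d$pm25[d$missing_pm25] <- NA
  d$pop_density_k <- d$pop_density / 1000
  d
}

grid_fit <- function(data, outcome, exposures, family, covariates, offset,
                     nAGQ, label_prefix) {
  fits <- list(); labels <- character(0)
  for (ex in exposures) {
    form <- if (ex %in% c("any_emitter_10km", "any_well_10km"))
      "binary" else "continuous"
    spec <- model_spec(outcome = outcome, exposure = ex, family = family,
                       covariates = covariates, offset = offset,
                       exposure_form = form, nAGQ = nAGQ,
                       scale_label = exposure_scales[[ex]])
    f <- tryCatch(fit_glmm(spec, data), error = function(e) e)
    if (inherits(f, "error")) {
      f <- structure(list(spec = spec, converged = FALSE,
                          error = conditionMessage(f), effect_estimate = NULL,
                          sigma_u = NA_real_),
                     class = "migrenv_fit")
    }
    fits[[length(fits) + 1]] <- f
    labels <- c(labels, paste(label_prefix, outcome, ex, sep = ":"))
  }
  names(fits) <- labels
  fits
}

#' Case-control model grid
#'
#' Four continuous-exposure logistic mixed models (PM2.5, NO2, IDW methane,
#' IDW wells), two binary-exposure secondary models, and (optionally) a
#' penalized-spline nonlinearity check for each continuous exposure. All
#' models use the standard adjustment set and a county random intercept.
#'
#' @param data Prepared analysis data (post-exclusions).
#' @param cfg A [study_config()].
#' @return List: `fits` (6 `migrenv_fit`s), `splines` (4 `spline_fit`s or
#'   `NULL`), `table` (effect table).
#' @export
run_case_control <- function(data, cfg = study_config()) {
  expos <- cfg$case_control_exposures
  cont <- intersect(c("pm25", "no2", "methane_idw", "well_idw"), expos)
  fits <- grid_fit(data, "is_case", expos, "logistic",
                   std_covariates, NULL, cfg$nAGQ, "cc")
  splines <- NULL
  if (isTRUE(cfg$run_splines)) {
    splines <- lapply(cont, function(ex) {
      spec <- model_spec("is_case", ex, "logistic", std_covariates,
                         exposure_form = "spline",
                         scale_label = exposure_scales[[ex]])
      tryCatch(spline_exposure_fit(spec, data), error = function(e) e)
    })
    names(splines) <- cont
  }
  list(fits = fits, splines = splines,
       table = effect_table(fits, names(fits)))
}

case_case_outcomes <- function() {
  list(
    neurology_visits = list(family = "negbin", offset = "person_years"),
    migraine_urgent_care = list(family = "negbin", offset = "person_years"),
    triptan_fills = list(family = "negbin", offset = "person_years"),
    any_migraine_ed = list(family = "logistic", offset = NULL),
    mpa_gt_100 = list(family = "logistic", offset = NULL)
  )
}

#' Case-case model grid
#'
#' Among cases only: 4 exposures x 5 severity outcomes with the correct
#' family per outcome (NB2 with log person-years offset for the three count
#' outcomes; logistic for the ED-visit and severe-score dichotomies), plus
#' optionally the 2 binary exposures x 5 outcomes secondary grid.
#'
#' @inheritParams run_case_control
#' @param binary Also fit the binary-exposure secondary grid (default from
#'   `cfg$run_case_case_binary`).
#' @return List: `fits` (named list), `table`.
#' @export
run_case_case <- function(data, cfg = study_config(),
                          binary = isTRUE(cfg$run_case_case_binary)) {
  cases <- data[data$is_case, , drop = FALSE]
  cont <- c("pm25", "no2", "methane_idw", "well_idw")
  bin <- if (binary) c("any_emitter_10km", "any_well_10km") else character(0)
  fits <- list()
  for (oc in names(case_case_outcomes())) {
    info <- case_case_outcomes()[[oc]]
    fits <- c(fits, grid_fit(cases, oc, c(cont, bin), info$family,
                             std_covariates, info$offset, cfg$nAGQ, "case"))
  }
  list(fits = fits, table = effect_table(fits, names(fits)))
}

#' Sensitivity analyses
#'
#' Three labeled re-runs of the fitted machinery:
#' \describe{
#'   \item{category_split}{case-control model with the IDW methane sum split
#'     into its dairy/landfill and other-industrial components (both terms
#'     in one model).}
#'   \item{bmi_marital}{main case-control grid re-fitted with additional
#'     adjustment for BMI category and marital status.}
#'   \item{distance_to_ed}{the ED-visit case-case models re-fitted with
#'     additional adjustment for great-circle distance to the nearest
#'     emergency department (ED locations: one per county, supplied or
#'     defaulting to the county centers).}
#' }
#'
#' @inheritParams run_case_control
#' @param region The study `region` (for default ED locations).
#' @param ed_locations Optional data frame with `lat`, `lon` of EDs.
#' @return Named list of result sets (each with `fits` and `table`).
#' @export
run_sensitivity <- function(data, cfg = study_config(), region = NULL,
                            ed_locations = NULL) {
  out <- list()
  sens <- cfg$sensitivity
  if (isTRUE(sens$category_split)) {
    cat_cols <- c("methane_idw_dairy_landfill", "methane_idw_other_industrial")
    # a category with no exposed patient carries no information; drop it
    usable <- cat_cols[vapply(cat_cols, function(cl)
      cl %in% names(data) && stats::var(data[[cl]], na.rm = TRUE) > 0,
      logical(1))]
    if (length(usable)) {
      spec <- model_spec(
        outcome = "is_case", exposure = usable[1], family = "logistic",
        covariates = c(usable[-1], std_covariates),
        nAGQ = cfg$nAGQ, scale_label = exposure_scales[["methane_idw"]])
      f <- tryCatch(fit_glmm(spec, data), error = function(e)
        structure(list(spec = spec, converged = FALSE,
                       error = conditionMessage(e), effect_estimate = NULL,
                       sigma_u = NA_real_), class = "migrenv_fit"))
      out$category_split <- list(
        fits = list(category_split = f),
        table = effect_table(list(f), "cc:is_case:methane_by_category"))
    }
  }
  if (isTRUE(sens$bmi_marital)) {
    covs <- c(std_covariates, "bmi_cat", "marital")
    fits <- grid_fit(data, "is_case",
                     c("pm25", "no2", "methane_idw", "well_idw"),
                     "logistic", covs, NULL, cfg$nAGQ, "cc_bmi_marital")
    out$bmi_marital <- list(fits = fits, table = effect_table(fits, names(fits)))
  }
  if (isTRUE(sens$distance_to_ed)) {
    if (is.null(ed_locations)) {
      if (is.null(region)) stop("need region or ed_locations for the ED-distance sensitivity")
      ed_locations <- region$counties
    }
    d <- data
    d$dist_ed_km <- distance_to_nearest_km(d$lat, d$lon,
                                           ed_locations$lat, ed_locations$lon)
    cases <- d[d$is_case, , drop = FALSE]
    fits <- grid_fit(cases, "any_migraine_ed",
                     c("pm25", "no2", "methane_idw", "well_idw"),
                     "logistic", c(std_covariates, "dist_ed_km"), NULL,
                     cfg$nAGQ, "case_ed_dist")
    out$distance_to_ed <- list(fits = fits,
                               table = effect_table(fits, names(fits)))
  }
  out
}

#' Run the full synthetic study end to end
#'
#' Generates geography, sources and a cohort from the configured ground
#' truth, scores and ascertains cases, frequency-matches controls, applies
#' the exclusion cascade, computes exposures, fits the case-control and
#' case-case model grids (plus configured sensitivity analyses), and runs
#' the Moran's I residual diagnostic on the case-control fits.
#'
#' @param cfg A [study_config()].
#' @return List with `region`, `sources`, `truth`, `cohort`,
#'   `ascertainment`, `matched`, `exclusions` (report), `analysis_data`,
#'   `case_control`, `case_case`, `sensitivity`, `moran` (data frame), and
#'   `tables` (all effect tables bound together).
#' @export
run_study <- function(cfg = study_config()) {
  region <- generate_region(cfg$n_counties, cfg$n_block_groups,
                            seed = cfg$seed)
  sources <- generate_sources(region, n_emitters = cfg$n_emitters,
                              n_wells = cfg$n_wells, seed = cfg$seed + 1)
  truth <- do.call(true_model, utils::modifyList(list(seed = cfg$seed + 2),
                                                 cfg$truth))
  cohort <- generate_cohort(region, sources, cfg$n_patients, truth,
                            radius_km = cfg$radius_km,
                            floor_km = cfg$floor_km,
                            p_outside = cfg$p_outside,
                            p_missing_poverty = cfg$p_missing_poverty,
                            p_missing_pm25 = cfg$p_missing_pm25)
  asc <- ascertain_cohort(cohort$patients, cohort$events)
  match_input <- merge(cohort$patients, asc[, c("patient_id", "is_case")],
                       by = "patient_id")
  matched <- frequency_match(match_input, ratio = cfg$match_ratio,
                             seed = cfg$seed + 3)
  keep_ids <- c(matched$cases, matched$controls)
  patients_m <- cohort$patients[cohort$patients$patient_id %in% keep_ids, ]
  ad <- prepare_analysis_data(patients_m, asc, region, sources, cfg)
  excl <- apply_exclusions(ad, county_filter = region$counties$county_id)
  ad <- excl$data
  message(sprintf("analysis data: %d cases, %d controls after exclusions",
                  sum(ad$is_case), sum(!ad$is_case)))
  cc <- run_case_control(ad, cfg)
  case_case <- if (isTRUE(cfg$run_case_case)) run_case_case(ad, cfg) else
    list(fits = list(), table = effect_table(list()))
  sens <- run_sensitivity(ad, cfg, region = region)
  moran_rows <- lapply(names(cc$fits), function(nm) {
    f <- cc$fits[[nm]]
    if (!isTRUE(f$converged)) return(NULL)
    m <- moran_diagnostic(f, ad, n_perm = cfg$moran_n_perm,
                          seed = cfg$seed + 4, max_n = cfg$moran_max_n)
    data.frame(model = nm, I = m$I, expected_I = m$expected_I,
               p_perm = m$p_perm, n_perm = m$n_perm,
               weight_scheme = m$weight_scheme, stringsAsFactors = FALSE)
  })
  moran <- do.call(rbind, Filter(Negate(is.null), moran_rows))
  tag <- function(tab, nm) if (nrow(tab)) cbind(analysis = nm, tab) else NULL
  pieces <- c(list(tag(cc$table, "case_control"),
                   tag(case_case$table, "case_case")),
              lapply(names(sens), function(nm)
                tag(sens[[nm]]$table, paste0("sensitivity_", nm))))
  tables <- do.call(rbind, Filter(Negate(is.null), pieces))
  list(region = region, sources = sources, truth = truth, cohort = cohort,
       ascertainment = asc, matched = matched, exclusions = excl$report,
       analysis_data = ad, case_control = cc, case_case = case_case,
       sensitivity = sens, moran = moran, tables = tables)
}
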