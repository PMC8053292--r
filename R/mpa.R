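#' Default migraine-probability scoring configuration
#'
#' The published score ranges over 0-101, is built from three component
#' classes (migraine-coded encounters, a significant-health-problem-list
#' flag, abortive-medication fills) and uses thresholds 10 (case) and 100
#' (more severe). The exact proprietary weight table is not public, so the
#' package ships a surrogate with the same structure: score =
#' min(101, w_enc * min(n_enc, cap_enc) + w_shp * 1{problem list} +
#' w_rx * min(n_fills, cap_rx)). All weights and caps are configurable.
#'
#' @return Named list of weights, caps and thresholds.
#' @export
mpa_default_config <- function() {
  list(w_enc = 20, cap_enc = 5,
       w_shp = 11,
       w_rx = 15, cap_rx = 3,
       score_max = 101, case_threshold = 10, severe_threshold = 100)
}

# event classes used throughout the package
EVENT_CLASSES <- c("migraine_encounter", "problem_list_migraine",
                   "abortive_fill", "neurology_visit",
                   "migraine_urgent_care", "migraine_ed", "other")

is_migraine_code <- function(code) {
  code <- toupper(trimws(as.character(code)))
  !is.na(code) & (startsWith(code, "346") | startsWith(code, "G43"))
}

#' Classify a single EHR event
#'
#' Prefix-based diagnosis matching ("346" for ICD-9, "G43" for ICD-10,
#' case-insensitive). Migraine-coded encounters are split by care setting:
#' emergency-department and urgent-care visits get their own classes (they
#' feed the severity outcomes); inpatient/outpatient/ED migraine encounters
#' all count toward the score's encounter component, urgent-care ones do
#' not. All-cause neurology visits are classified by setting alone.
#' Malformed inputs fall through to `"other"`; this function never raises.
#'
#' @param event_type `"encounter"`, `"prescription"` or `"problem_list"`.
#' @param code Diagnosis code string (may be `NA` or malformed).
#' @param care_setting One of `"outpatient"`, `"inpatient"`, `"ed"`,
#'   `"urgent_care"`, `"neurology"` (encounters only).
#' @param medication_class Medication class label (prescriptions only);
#'   `"triptan"` or `"ergotamine"` mark migraine-specific abortives.
#' @return One of `migraine_encounter`, `problem_list_migraine`,
#'   `abortive_fill`, `neurology_visit`, `migraine_urgent_care`,
#'   `migraine_ed`, `other`. Vectorized.
#' @export
classify_event <- function(event_type, code = NA, care_setting = NA,
                           medication_class = NA) {
  n <- max(length(event_type), length(code), length(care_setting),
           length(medication_class))
  event_type <- rep_len(tolower(as.character(event_type)), n)
  code <- rep_len(as.character(code), n)
  care_setting <- rep_len(tolower(as.character(care_setting)), n)
  medication_class <- rep_len(tolower(as.character(medication_class)), n)

  out <- rep("other", n)
  mig <- is_migraine_code(code)
  enc <- event_type == "encounter"
  out[enc & care_setting == "neurology"] <- "neurology_visit"
  out[enc & mig & care_setting %in% c("outpatient", "inpatient")] <- "migraine_encounter"
  out[enc & mig & care_setting == "ed"] <- "migraine_ed"
  out[enc & mig & care_setting == "urgent_care"] <- "migraine_urgent_care"
  out[event_type == "problem_list" & mig] <- "problem_list_migraine"
  out[event_type == "prescription" &
        medication_class %in% c("triptan", "ergotamine")] <- "abortive_fill"
  out
}

#' Score one patient's event stream
#'
#' @param events Data frame of one patient's events with columns
#'   `event_type`, `code`, `care_setting`, `medication_class` (zero rows
#'   allowed).
#' @param config Scoring configuration, see [mpa_default_config()].
#' @return Object of class `mpa_result`: list with `score` (integer in
#'   [0, 101]), `is_case` (score > 10), `severe` (score > 100) and
#'   `component_counts` (encounters, problem-list flag, fills).
#' @export
mpa_score <- function(events, config = mpa_default_config()) {
  cls <- if (nrow(events) == 0) character(0) else
    classify_event(events$event_type, events$code, events$care_setting,
                   events$medication_class)
  n_enc <- sum(cls %in% c("migraine_encounter", "migraine_ed"))
  shp <- any(cls == "problem_list_migraine")
  n_rx <- sum(cls == "abortive_fill")
  raw <- config$w_enc * min(n_enc, config$cap_enc) +
    config$w_shp * as.integer(shp) +
    config$w_rx * min(n_rx, config$cap_rx)
  score <- min(config$score_max, raw)
  structure(list(
    score = score,
    is_case = score > config$case_threshold,
    severe = score > config$severe_threshold,
    component_counts = c(encounters = n_enc, problem_list = as.integer(shp),
                         fills = n_rx)
  ), class = "mpa_result")
}

#' Severity outcomes for a migraine case
#'
#' Three rates per person-year (all-cause neurology visits, migraine-specific
#' urgent care visits, triptan/abortive fills) plus two dichotomies: at least
#' one migraine-specific emergency-department visit during the window, and a
#' score above the severe threshold.
#'
#' @param events The case's event data frame (as in [mpa_score()]).
#' @param mpa The case's `mpa_result`; must satisfy `is_case`.
#' @param person_years Follow-up in person-years (> 0).
#' @return Object of class `severity_outcomes`: list with counts
#'   (`neurology_visits`, `migraine_urgent_care`, `triptan_fills`,
#'   `migraine_ed_visits`), per-person-year rates (`*_per_py`),
#'   `any_migraine_ed`, `mpa_gt_100` and `person_years`.
#' @export
severity_outcomes <- function(events, mpa, person_years) {
  if (!inherits(mpa, "mpa_result") || !mpa$is_case)
    stop("severity outcomes are defined for cases only (score > threshold)")
  if (!is.numeric(person_years) || person_years <= 0)
    stop("person_years must be > 0")
  cls <- if (nrow(events) == 0) character(0) else
    classify_event(events$event_type, events$code, events$care_setting,
                   events$medication_class)
  n_neuro <- sum(cls == "neurology_visit")
  n_uc <- sum(cls == "migraine_urgent_care")
  n_rx <- sum(cls == "abortive_fill")
  n_ed <- sum(cls == "migraine_ed")
  structure(list(
    neurology_visits = n_neuro,
    migraine_urgent_care = n_uc,
    triptan_fills = n_rx,
    migraine_ed_visits = n_ed,
    neurology_visits_per_py = n_neuro / person_years,
    migraine_urgent_care_per_py = n_uc / person_years,
    triptans_per_py = n_rx / person_years,
    any_migraine_ed = n_ed >= 1,
    mpa_gt_100 = mpa$severe,
    person_years = person_years
  ), class = "severity_outcomes")
}

#' Ascertain case status and severity for a whole cohort
#'
#' Scores every patient from the events table, flags cases, and builds the
#' severity table for cases.
#'
#' @param patients Patient data frame with `patient_id` and `person_years`.
#' @param events Events data frame with a `patient_id` column.
#' @param config Scoring configuration.
#' @return Data frame keyed by `patient_id` with `mpa_score`, `is_case`,
#'   `mpa_gt_100`, component counts, severity counts and rates (`NA` for
#'   non-cases), and `person_years`.
#' @export
ascertain_cohort <- function(patients, events, config = mpa_default_config()) {
  cls <- if (nrow(events) == 0) character(0) else
    classify_event(events$event_type, events$code, events$care_setting,
                   events$medication_class)
  tab <- function(class_set) {
    idx <- cls %in% class_set
    cnt <- table(factor(events$patient_id[idx], levels = patients$patient_id))
    as.integer(cnt)
  }
  n_enc <- tab(c("migraine_encounter", "migraine_ed"))
  n_shp <- tab("problem_list_migraine")
  n_rx <- tab("abortive_fill")
  n_neuro <- tab("neurology_visit")
  n_uc <- tab("migraine_urgent_care")
  n_ed <- tab("migraine_ed")
  raw <- config$w_enc * pmin(n_enc, config$cap_enc) +
    config$w_shp * as.integer(n_shp > 0) +
    config$w_rx * pmin(n_rx, config$cap_rx)
  score <- pmin(config$score_max, raw)
  is_case <- score > config$case_threshold
  py <- patients$person_years
  out <- data.frame(
    patient_id = patients$patient_id,
    mpa_score = score,
    is_case = is_case,
    mpa_gt_100 = score > config$severe_threshold,
    n_migraine_encounters = n_enc,
    problem_list = n_shp > 0,
    n_abortive_fills = n_rx,
    neurology_visits = n_neuro,
    migraine_urgent_care = n_uc,
    triptan_fills = n_rx,
    migraine_ed_visits = n_ed,
    person_years = py,
    stringsAsFactors = FALSE
  )
  out$neurology_visits_per_py <- ifelse(is_case, n_neuro / py, NA_real_)
  out$migraine_urgent_care_per_py <- ifelse(is_case, n_uc / py, NA_real_)
  out$triptans_per_py <- ifelse(is_case, n_rx / py, NA_real_)
  out$any_migraine_ed <- ifelse(is_case, n_ed >= 1, NA)
  out
}
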