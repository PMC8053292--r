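#' Frequency-match controls to cases
#'
#' Within each joint stratum of the four matching variables (age category,
#' sex, entry year, follow-up category), samples `min(ratio * n_cases,
#' available)` candidates uniformly without replacement. Strata with fewer
#' candidates than the target keep everything available and the shortfall is
#' reported; strata are never relaxed.
#'
#' @param cohort Data frame with columns `patient_id`, `is_case`, `age_cat`,
#'   `sex`, `entry_year`, `followup_cat`. Rows with `is_case == TRUE` are
#'   the cases; the remaining rows form the candidate pool (the two sets are
#'   disjoint by construction).
#' @param ratio Target controls per case (default 3).
#' @param seed Seed for the within-stratum sampling.
#' @param vars Matching variables.
#' @return Object of class `matched_cohort`: `cases` and `controls` (id
#'   vectors), `strata` (data frame with per-stratum case/candidate/selected
#'   counts, achieved ratio and shortfall), and `ratio`.
#' @export
frequency_match <- function(cohort, ratio = 3, seed = 1,
                            vars = c("age_cat", "sex", "entry_year",
                                     "followup_cat")) {
  stopifnot(all(c("patient_id", "is_case", vars) %in% names(cohort)))
  cases <- cohort[cohort$is_case, , drop = FALSE]
  pool <- cohort[!cohort$is_case, , drop = FALSE]
  if (nrow(cases) == 0) stop("no cases to match")
  key <- function(d) do.call(paste, c(d[vars], sep = "|"))
  cases$.k <- key(cases)
  pool$.k <- key(pool)
  strata_keys <- sort(unique(cases$.k))
  local_seed(seed)
  sel <- character(0)
  rows <- vector("list", length(strata_keys))
  for (s in seq_along(strata_keys)) {
    kk <- strata_keys[s]
    n_cases <- sum(cases$.k == kk)
    cand <- pool$patient_id[pool$.k == kk]
    target <- ratio * n_cases
    take <- min(target, length(cand))
    chosen <- if (take > 0) sample(cand, take) else character(0)
    sel <- c(sel, chosen)
    rows[[s]] <- data.frame(stratum = kk, n_cases = n_cases,
                            n_candidates = length(cand),
                            n_controls = take,
                            achieved_ratio = take / n_cases,
                            shortfall = target - take,
                            stringsAsFactors = FALSE)
  }
  strata <- do.call(rbind, rows)
  if (any(strata$shortfall > 0)) {
    message(sum(strata$shortfall > 0),
            " matching strata short of the target ratio (",
            sum(strata$shortfall), " controls short in total)")
  }
  structure(list(cases = cases$patient_id, controls = sel,
                 strata = strata, ratio = ratio),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "Matched cohort: %d cases, %d controls (target %d:1) in %d strata; %d strata short\n",
    length(x$cases), length(x$controls), x$ratio, nrow(x$strata),
    sum(x$strata$shortfall > 0)))
  invisible(x)
}
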