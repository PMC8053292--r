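#' Inverse-distance-squared sum of methane emissions near a residence
#'
#' Aggregates emission rates of all point sources within `radius_km` of a
#' residence, each weighted by the inverse of its squared distance:
#' sum over sources i of E_i / d_ij^2, with E_i in kg/hour and d_ij in km.
#' The buffer is closed (a source at exactly `radius_km` counts) and
#' distances are floored at `floor_km` before squaring so that a co-located
#' source cannot dominate the sum.
#'
#' @param lat,lon Residence coordinates (degrees, or planar km when
#'   `metric = "planar"`).
#' @param sources A `source_set` (only its `emitters` are used) or a data
#'   frame with columns `lat`, `lon`, `emission_kg_hr` and optionally
#'   `category`.
#' @param radius_km Buffer radius in km (default 10).
#' @param floor_km Minimum distance in km applied before squaring
#'   (default 0.05).
#' @param metric `"geodesic"` (haversine; default) or `"planar"`.
#' @param by_category If `TRUE`, also return the per-category decomposition.
#' @return The IDW emission sum in kg/hour·km^-2 (0 when no source lies within
#'   the buffer). With `by_category = TRUE`, a list with elements `total` and
#'   `by_category` (named numeric vector).
#' @export
idw_emission_sum <- function(lat, lon, sources, radius_km = 10,
                             floor_km = 0.05, metric = c("geodesic", "planar"),
                             by_category = FALSE) {
  metric <- match.arg(metric)
  if (radius_km <= 0) stop("radius_km must be > 0")
  em <- if (inherits(sources, "source_set")) sources$emitters else sources
  if (is.null(em) || nrow(em) == 0) {
    if (by_category) return(list(total = 0, by_category = numeric(0)))
    return(0)
  }
  if (any(em$emission_kg_hr <= 0)) stop("emission rates must be > 0")
  d <- dist_fun(metric)(lat, lon, em$lat, em$lon)
  keep <- d <= radius_km
  w <- em$emission_kg_hr[keep] / pmax(d[keep], floor_km)^2
  total <- sum(w)
  if (!by_category) return(total)
  cat <- if ("category" %in% names(em)) em$category[keep] else rep("all", sum(keep))
  by_cat <- if (length(w)) tapply(w, cat, sum) else numeric(0)
  list(total = total, by_category = c(by_cat))
}

#' Inverse-distance-squared sum of active wells near a residence
#'
#' As [idw_emission_sum()] with every source's magnitude fixed at 1: sum of
#' 1/d_ij^2 over *active* wells within the buffer. Inactive wells never
#' contribute.
#'
#' @inheritParams idw_emission_sum
#' @param sources A `source_set` (only its `wells` are used) or a data frame
#'   with columns `lat`, `lon`, `active`.
#' @return The IDW well sum in km^-2 (0 when no active well within buffer).
#' @export
idw_well_sum <- function(lat, lon, sources, radius_km = 10, floor_km = 0.05,
                         metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  if (radius_km <= 0) stop("radius_km must be > 0")
  wl <- if (inherits(sources, "source_set")) sources$wells else sources
  if (is.null(wl) || nrow(wl) == 0) return(0)
  wl <- wl[wl$active, , drop = FALSE]
  if (nrow(wl) == 0) return(0)
  d <- dist_fun(metric)(lat, lon, wl$lat, wl$lon)
  keep <- d <= radius_km
  sum(1 / pmax(d[keep], floor_km)^2)
}

dist_fun <- function(metric) {
  if (metric == "geodesic") {
    function(lat, lon, lat2, lon2) haversine_km(lat, lon, lat2, lon2)
  } else {
    function(lat, lon, lat2, lon2) euclidean_km(lat, lon, lat2, lon2)
  }
}

#' Link a patient to block-group covariates
#'
#' Returns the pollutant and socioeconomic values of the patient's block
#' group verbatim. An unknown block-group id is a missing-linkage error; the
#' pipeline treats such records as exclusions.
#'
#' @param bg_id Block-group id (scalar character).
#' @param region A `region` object.
#' @return Named list: `pm25`, `no2`, `poverty_pct`, `pop_density`.
#' @export
link_block_group <- function(bg_id, region) {
  stopifnot(inherits(region, "region"))
  i <- match(bg_id, region$block_groups$bg_id)
  if (is.na(i)) stop("unknown block-group id: ", bg_id)
  bg <- region$block_groups[i, ]
  list(pm25 = bg$pm25, no2 = bg$no2,
       poverty_pct = bg$poverty_pct, pop_density = bg$pop_density)
}

#' Compute the full per-patient exposure table
#'
#' For each patient: block-group pollutant linkage (PM2.5, NO2), the IDW
#' methane emission sum, the IDW active-well sum, the two binary 10-km
#' source-presence indicators, and the per-category methane decomposition.
#'
#' @param patients Data frame with columns `patient_id`, `lat`, `lon`,
#'   `bg_id`.
#' @param region A `region` object.
#' @param sources A `source_set`. An empty set is allowed; IDW columns are
#'   then zero and indicators `FALSE`.
#' @inheritParams idw_emission_sum
#' @return Data frame keyed by `patient_id` with columns `pm25`, `no2`,
#'   `methane_idw`, `well_idw`, `any_emitter_10km`, `any_well_10km`,
#'   `methane_idw_dairy_landfill`, `methane_idw_other_industrial`. Patients
#'   whose block group is absent from the region get `NA` pollutant values
#'   (they are removed later by the exclusion step).
#' @export
compute_exposures <- function(patients, region, sources, radius_km = 10,
                              floor_km = 0.05,
                              metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  stopifnot(inherits(region, "region"))
  n <- nrow(patients)
  bg <- region$block_groups
  i <- match(patients$bg_id, bg$bg_id)
  out <- data.frame(
    patient_id = patients$patient_id,
    pm25 = bg$pm25[i],
    no2 = bg$no2[i],
    poverty_pct = bg$poverty_pct[i],
    pop_density = bg$pop_density[i],
    methane_idw = numeric(n),
    well_idw = numeric(n),
    any_emitter_10km = logical(n),
    any_well_10km = logical(n),
    methane_idw_dairy_landfill = numeric(n),
    methane_idw_other_industrial = numeric(n),
    stringsAsFactors = FALSE
  )
  em <- sources$emitters
  wl <- sources$wells
  wl_act <- if (nrow(wl)) wl[wl$active, , drop = FALSE] else wl
  dfun <- dist_fun(metric)
  # loop over sources, not patients: source sets are sparse
  if (nrow(em)) {
    for (k in seq_len(nrow(em))) {
      d <- dfun(patients$lat, patients$lon, em$lat[k], em$lon[k])
      keep <- d <= radius_km
      w <- ifelse(keep, em$emission_kg_hr[k] / pmax(d, floor_km)^2, 0)
      out$methane_idw <- out$methane_idw + w
      out$any_emitter_10km <- out$any_emitter_10km | keep
      col <- paste0("methane_idw_", em$category[k])
      if (!col %in% names(out)) out[[col]] <- 0
      out[[col]] <- out[[col]] + w
    }
  }
  if (nrow(wl_act)) {
    for (k in seq_len(nrow(wl_act))) {
      d <- dfun(patients$lat, patients$lon, wl_act$lat[k], wl_act$lon[k])
      keep <- d <= radius_km
      out$well_idw <- out$well_idw + ifelse(keep, 1 / pmax(d, floor_km)^2, 0)
      out$any_well_10km <- out$any_well_10km | keep
    }
  }
  out
}

#' Rescale exposures to the reporting units
#'
#' Divides PM2.5 and NO2 by 5 (per 5 µg/m³ / per 5 ppb), the IDW methane sum
#' by 100,000 (per 100,000 kg/hour) and the IDW well sum by 1000 (per
#' 1000-unit increase), so that model coefficients are log-OR/log-RR per
#' rescaled unit. Binary indicators are unchanged.
#'
#' @param exposures Data frame from [compute_exposures()] (or any frame with
#'   a subset of the four continuous columns).
#' @param constants Named rescaling divisors; defaults
#'   `c(pm25 = 5, no2 = 5, methane_idw = 1e5, well_idw = 1e3)`.
#' @return The data frame with the continuous exposure columns divided by
#'   their constants (category decompositions share the methane constant).
#' @export
rescale_exposures <- function(exposures,
                              constants = c(pm25 = 5, no2 = 5,
                                            methane_idw = 1e5,
                                            well_idw = 1e3)) {
  if (any(constants <= 0)) stop("rescale constants must be > 0")
  for (nm in names(constants)) {
    if (nm %in% names(exposures))
      exposures[[nm]] <- exposures[[nm]] / constants[[nm]]
  }
  for (col in grep("^methane_idw_", names(exposures), value = TRUE)) {
    exposures[[col]] <- exposures[[col]] / constants[["methane_idw"]]
  }
  exposures
}
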