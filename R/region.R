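#' Generate a synthetic study region
#'
#' Builds a region of counties and census block groups with smooth pollutant
#' surfaces and block-group socioeconomic covariates. Block-group centroids
#' are spatially clustered around county centers; the PM2.5 and NO2 surfaces
#' are a low-order spatial trend plus smooth Gaussian-bump noise, rescaled
#' into the observed concentration ranges so that neighboring block groups
#' carry correlated values.
#'
#' @param n_counties Number of counties (>= 1).
#' @param n_block_groups Number of block groups (>= n_counties); every county
#'   receives at least one.
#' @param seed Integer seed; identical seeds give identical regions.
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#'   Default covers a Northern-California-sized area.
#' @param pm25_range,no2_range Ranges (µg/m³, ppb) into which the pollutant
#'   surfaces are rescaled. Defaults are the observed study ranges
#'   [3.7, 13.3] µg/m³ and [1.1, 15.2] ppb.
#' @return An object of class `region`: a list with data frames `counties`
#'   (`county_id`, `lat`, `lon`) and `block_groups` (`bg_id`, `county_id`,
#'   `lat`, `lon`, `poverty_pct`, `pop_density`, `pm25`, `no2`).
#' @export
generate_region <- function(n_counties, n_block_groups, seed,
                            bbox = c(-123.5, -120.0, 36.5, 40.0),
                            pm25_range = c(3.7, 13.3),
                            no2_range = c(1.1, 15.2)) {
  if (n_counties < 1) stop("n_counties must be >= 1")
  if (n_block_groups < n_counties)
    stop("n_block_groups must be >= n_counties")
  rng <- local_seed(seed)
  lon0 <- bbox[1]; lon1 <- bbox[2]; lat0 <- bbox[3]; lat1 <- bbox[4]

  counties <- data.frame(
    county_id = sprintf("C%02d", seq_len(n_counties)),
    lon = stats::runif(n_counties, lon0, lon1),
    lat = stats::runif(n_counties, lat0, lat1),
    stringsAsFactors = FALSE
  )

  # each county gets one block group, remainder multinomial
  extra <- n_block_groups - n_counties
  alloc <- rep(1L, n_counties)
  if (extra > 0) {
    draw <- sample.int(n_counties, extra, replace = TRUE)
    alloc <- alloc + tabulate(draw, nbins = n_counties)
  }
  cidx <- rep(seq_len(n_counties), alloc)
  scatter_deg <- 0.15  # ~15 km cluster scale
  bg_lon <- pmin(pmax(counties$lon[cidx] + stats::rnorm(n_block_groups, 0, scatter_deg), lon0), lon1)
  bg_lat <- pmin(pmax(counties$lat[cidx] + stats::rnorm(n_block_groups, 0, scatter_deg), lat0), lat1)

  pm25 <- smooth_surface(bg_lon, bg_lat, bbox, pm25_range)
  no2 <- smooth_surface(bg_lon, bg_lat, bbox, no2_range)

  bg <- data.frame(
    bg_id = sprintf("BG%05d", seq_len(n_block_groups)),
    county_id = counties$county_id[cidx],
    lat = bg_lat,
    lon = bg_lon,
    poverty_pct = 100 * stats::rbeta(n_block_groups, 2, 22),
    pop_density = stats::rlnorm(n_block_groups, log(2250), 1.0),
    pm25 = pm25,
    no2 = no2,
    stringsAsFactors = FALSE
  )
  structure(list(counties = counties, block_groups = bg), class = "region")
}

# Low-order trend plus a handful of broad Gaussian bumps, min-max rescaled
# into `range`. Values at nearby coordinates are correlated by construction.
smooth_surface <- function(lon, lat, bbox, range) {
  u <- (lon - bbox[1]) / (bbox[2] - bbox[1])
  v <- (lat - bbox[3]) / (bbox[4] - bbox[3])
  z <- stats::runif(1, -1, 1) * u + stats::runif(1, -1, 1) * v
  n_bump <- 6
  cu <- stats::runif(n_bump); cv <- stats::runif(n_bump)
  amp <- stats::rnorm(n_bump, 0, 1); rho <- stats::runif(n_bump, 0.15, 0.4)
  for (m in seq_len(n_bump)) {
    z <- z + amp[m] * exp(-((u - cu[m])^2 + (v - cv[m])^2) / (2 * rho[m]^2))
  }
  if (diff(range(z)) < .Machine$double.eps) return(rep(mean(range), length(z)))
  range[1] + (z - min(z)) / (max(z) - min(z)) * (range[2] - range[1])
}

#' Generate synthetic methane point sources and oil/gas wells
#'
#' Sparse point sources scattered over the region bounding box: methane
#' super-emitters with lognormal hourly emission rates split between
#' dairy/landfill and other industrial categories, and wells with an active
#' flag.
#'
#' @param region A `region` object.
#' @param n_emitters Number of methane super-emitters (default 60, the number
#'   located near study participants).
#' @param n_wells Number of wells (default 2000).
#' @param seed Integer seed.
#' @param p_dairy_landfill Probability an emitter is in the `dairy_landfill`
#'   category (default 35/60, the surveyed split of nearby sources).
#' @param p_active Probability a well is active (default 0.85).
#' @param rate_meanlog,rate_sdlog Lognormal parameters for emission rates in
#'   kg/hour. Defaults give typical super-emitter rates in the hundreds to
#'   thousands of kg/hour with a heavy upper tail.
#' @param n_well_fields Wells cluster around this many field centers rather
#'   than scattering uniformly (oil and gas wells sit in fields); keeps the
#'   fraction of residences with any well within 10 km realistic (~10-20%).
#' @param field_sd_km Spatial SD of a well field in km.
#' @param field_offset_km SD of the displacement of field centers from their
#'   anchor block group in km; fields sit near but rarely on top of towns.
#' @return Object of class `source_set`: list with data frames `emitters`
#'   (`emitter_id`, `lat`, `lon`, `category`, `emission_kg_hr`) and `wells`
#'   (`well_id`, `lat`, `lon`, `active`).
#' @export
generate_sources <- function(region, n_emitters = 60, n_wells = 2000, seed = 1,
                             p_dairy_landfill = 35 / 60, p_active = 0.85,
                             rate_meanlog = log(2000), rate_sdlog = 1.5,
                             n_well_fields = 6, field_sd_km = 4,
                             field_offset_km = 15) {
  stopifnot(inherits(region, "region"))
  rng <- local_seed(seed)
  bb <- region_bbox(region)
  bg <- region$block_groups
  # half the emitters sit near populated places (dairies, landfills and
  # refineries serve towns), producing the occasional very close residence
  # and hence the heavy-tailed IDW distribution seen in practice
  near <- stats::runif(n_emitters) < 0.3
  anchor <- sample.int(nrow(bg), n_emitters, replace = TRUE)
  e_lon <- ifelse(near, bg$lon[anchor] + stats::rnorm(n_emitters, 0, 2 / 111.19),
                  stats::runif(n_emitters, bb[1], bb[2]))
  e_lat <- ifelse(near, bg$lat[anchor] + stats::rnorm(n_emitters, 0, 2 / 111.19),
                  stats::runif(n_emitters, bb[3], bb[4]))
  emitters <- data.frame(
    emitter_id = sprintf("E%04d", seq_len(n_emitters)),
    lon = e_lon,
    lat = e_lat,
    category = ifelse(stats::runif(n_emitters) < p_dairy_landfill,
                      "dairy_landfill", "other_industrial"),
    emission_kg_hr = stats::rlnorm(n_emitters, rate_meanlog, rate_sdlog),
    stringsAsFactors = FALSE
  )
  # well fields anchor near (not on) block groups: historic fields border
  # towns, so a minority of residences fall inside a field's 10 km reach
  fi <- sample.int(n_well_fields, n_wells, replace = TRUE)
  fa <- sample.int(nrow(bg), n_well_fields, replace = TRUE)
  off_deg <- field_offset_km / 111.19
  f_lon <- bg$lon[fa] + stats::rnorm(n_well_fields, 0, off_deg)
  f_lat <- bg$lat[fa] + stats::rnorm(n_well_fields, 0, off_deg)
  sd_deg <- field_sd_km / 111.19
  wells <- data.frame(
    well_id = sprintf("W%05d", seq_len(n_wells)),
    lon = f_lon[fi] + stats::rnorm(n_wells, 0, sd_deg),
    lat = f_lat[fi] + stats::rnorm(n_wells, 0, sd_deg),
    active = stats::runif(n_wells) < p_active,
    stringsAsFactors = FALSE
  )
  structure(list(emitters = emitters, wells = wells), class = "source_set")
}

#' Construct a source set from raw tables
#'
#' @param emitters Data frame with columns `emitter_id`, `lat`, `lon`,
#'   `category`, `emission_kg_hr` (rates must be > 0). May have zero rows.
#' @param wells Data frame with columns `well_id`, `lat`, `lon`, `active`.
#' @return A `source_set` object.
#' @export
source_set <- function(emitters = NULL, wells = NULL) {
  empty_e <- data.frame(emitter_id = character(), lat = numeric(),
                        lon = numeric(), category = character(),
                        emission_kg_hr = numeric(), stringsAsFactors = FALSE)
  empty_w <- data.frame(well_id = character(), lat = numeric(),
                        lon = numeric(), active = logical(),
                        stringsAsFactors = FALSE)
  if (is.null(emitters)) emitters <- empty_e
  if (is.null(wells)) wells <- empty_w
  if (nrow(emitters) && any(emitters$emission_kg_hr <= 0))
    stop("emission rates must be > 0")
  structure(list(emitters = emitters, wells = wells), class = "source_set")
}

region_bbox <- function(region) {
  bg <- region$block_groups
  c(min(bg$lon) - 0.1, max(bg$lon) + 0.1, min(bg$lat) - 0.1, max(bg$lat) + 0.1)
}

local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  set.seed(as.integer(seed))
  invisible(seed)
}
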