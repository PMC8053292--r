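test_that("haversine distance matches the great-circle closed form", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  # one degree of longitude along the equator: R * pi/180
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  # symmetry on random pairs
  set.seed(4)
  a <- cbind(runif(20, -90, 90), runif(20, -180, 180))
  b <- cbind(runif(20, -90, 90), runif(20, -180, 180))
  expect_equal(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_km(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_true(all(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]) >= 0))
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 190, 0, 0), "longitude")
})

test_that("IDW emission sum follows the inverse-distance-squared formula", {
  # planar coordinates in km make distances exact
  em <- function(d, E) data.frame(lat = d, lon = 0, emission_kg_hr = E)
  # unit distance: 100 kg/h at 1 km -> 100
  expect_equal(idw_emission_sum(0, 0, em(1, 100), metric = "planar"), 100)
  # nothing within 10 km -> 0
  expect_equal(idw_emission_sum(0, 0, em(12, 500), metric = "planar"), 0)
  # mixed set with one source outside the buffer: 200/4 + 50/25 = 52
  src <- data.frame(lat = c(2, 5, 11), lon = 0,
                    emission_kg_hr = c(200, 50, 10))
  expect_equal(idw_emission_sum(0, 0, src, metric = "planar"), 52)
  # closed buffer: source at exactly 10 km included
  expect_equal(idw_emission_sum(0, 0, em(10, 100), metric = "planar"), 1)
  # distance floor: co-located source capped at floor_km
  expect_equal(idw_emission_sum(0, 0, em(0.01, 10), metric = "planar"),
               10 / 0.05^2)
  # rates must be positive
  expect_error(idw_emission_sum(0, 0, em(1, -5), metric = "planar"))
})

test_that("IDW well sum counts only active wells", {
  wl <- function(d, active) data.frame(lat = d, lon = 0, active = active)
  expect_equal(idw_well_sum(0, 0, wl(1, TRUE), metric = "planar"), 1)
  expect_equal(idw_well_sum(0, 0, wl(1, FALSE), metric = "planar"), 0)
  # 4 active wells at 2 km: 4 * 1/4 = 1
  w4 <- data.frame(lat = c(2, -2, 0, 0), lon = c(0, 0, 2, -2), active = TRUE)
  expect_equal(idw_well_sum(0, 0, w4, metric = "planar"), 1)
})

test_that("IDW sums agree with the brute-force oracle on random fields", {
  set.seed(77)
  for (rep in 1:25) {
    n_src <- sample(1:200, 1)
    lat0 <- runif(1, 36, 40)
    lon0 <- runif(1, -123, -120)
    src <- data.frame(
      lat = lat0 + runif(n_src, -0.3, 0.3),
      lon = lon0 + runif(n_src, -0.3, 0.3),
      emission_kg_hr = rlnorm(n_src, 3, 1),
      active = runif(n_src) < 0.7)
    got <- idw_emission_sum(lat0, lon0, src)
    want <- brute_idw(lat0, lon0, src$lat, src$lon, src$emission_kg_hr)
    expect_equal(got, want, tolerance = 1e-10)
    got_w <- idw_well_sum(lat0, lon0, src)
    act <- src[src$active, ]
    want_w <- brute_idw(lat0, lon0, act$lat, act$lon, rep(1, nrow(act)))
    expect_equal(got_w, want_w, tolerance = 1e-10)
  }
})

test_that("IDW is monotone in sources and emission rates", {
  set.seed(5)
  src <- data.frame(lat = runif(10, -0.05, 0.05), lon = runif(10, -0.05, 0.05),
                    emission_kg_hr = rlnorm(10, 3, 1))
  base <- idw_emission_sum(0, 0, src)
  # adding an in-radius source increases the sum
  more <- rbind(src, data.frame(lat = 0.01, lon = 0.01, emission_kg_hr = 5))
  expect_gt(idw_emission_sum(0, 0, more), base)
  # increasing any E_i strictly increases the sum
  src2 <- src
  src2$emission_kg_hr[3] <- src2$emission_kg_hr[3] * 2
  expect_gt(idw_emission_sum(0, 0, src2), base)
})

test_that("category decomposition sums to the total methane IDW", {
  r <- tiny_region()
  s <- tiny_sources(r)
  tr <- true_model(seed = 3)
  co <- generate_cohort(r, s, 300, tr, events = FALSE)
  e <- compute_exposures(co$patients, r, s)
  expect_equal(e$methane_idw,
               e$methane_idw_dairy_landfill + e$methane_idw_other_industrial,
               tolerance = 1e-12)
  # presence indicators match positive sums
  expect_equal(e$any_emitter_10km, e$methane_idw > 0)
  expect_true(all(e$methane_idw >= 0 & e$well_idw >= 0))
  expect_true(all(e$pm25 > 0 & e$no2 > 0))
})

test_that("block-group linkage returns values verbatim and errors on unknowns", {
  r <- tiny_region()
  bg <- r$block_groups[5, ]
  got <- link_block_group(bg$bg_id, r)
  expect_equal(got$pm25, bg$pm25)
  expect_equal(got$no2, bg$no2)
  expect_equal(got$poverty_pct, bg$poverty_pct)
  expect_equal(got$pop_density, bg$pop_density)
  expect_error(link_block_group("BG99999", r), "unknown block-group")
  # two patients in the same block group link identically
  expect_identical(link_block_group(bg$bg_id, r), got)
})

test_that("rescaling divides by the reporting-unit constants", {
  prof <- data.frame(pm25 = 10, no2 = 7.5, methane_idw = 250000,
                     well_idw = 1500, any_emitter_10km = TRUE,
                     any_well_10km = FALSE,
                     methane_idw_dairy_landfill = 150000,
                     methane_idw_other_industrial = 100000)
  r <- rescale_exposures(prof)
  expect_equal(r$pm25, 2)
  expect_equal(r$no2, 1.5)
  expect_equal(r$methane_idw, 2.5)
  expect_equal(r$well_idw, 1.5)
  expect_identical(r$any_emitter_10km, TRUE)
  expect_equal(r$methane_idw_dairy_landfill +
                 r$methane_idw_other_industrial, 2.5)
  # all-zero IDW profile stays zero
  z <- rescale_exposures(data.frame(methane_idw = 0, well_idw = 0))
  expect_equal(unlist(z), c(methane_idw = 0, well_idw = 0))
  expect_error(rescale_exposures(prof, constants = c(pm25 = -1)))
})
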