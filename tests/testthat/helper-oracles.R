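# Independent oracles, deliberately naive, used to verify package results.

# all-pairs brute-force IDW over a source table (planar or geodesic)
brute_idw <- function(lat, lon, src_lat, src_lon, magnitude, radius_km = 10,
                      floor_km = 0.05, planar = FALSE) {
  total <- 0
  for (i in seq_along(src_lat)) {
    d <- if (planar) {
      sqrt((lat - src_lat[i])^2 + (lon - src_lon[i])^2)
    } else {
      haversine_km(lat, lon, src_lat[i], src_lon[i])
    }
    if (d <= radius_km) total <- total + magnitude[i] / max(d, floor_km)^2
  }
  total
}

# naive double-loop Moran's I from a triplet weight list
naive_moran <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  W <- 0
  num <- 0
  for (t in seq_along(w$i)) {
    num <- num + w$w[t] * z[w$i[t]] * z[w$j[t]]
    W <- W + w$w[t]
  }
  (n / W) * num / sum(z^2)
}

# dense numerical integration of the random-intercept marginal loglik
# (midpoint rule on a wide grid), independent of the package's quadrature
dense_loglik <- function(y, eta0, group, sigma, family = "logistic",
                         alpha = NA, n_grid = 10000, width = 10) {
  gl <- unique(group)
  bs <- seq(-width * sigma, width * sigma, length.out = n_grid)
  h <- bs[2] - bs[1]
  total <- 0
  for (g in gl) {
    idx <- group == g
    s <- vapply(bs, function(b) {
      if (family == "logistic") {
        sum(stats::dbinom(y[idx], 1, stats::plogis(eta0[idx] + b), log = TRUE))
      } else {
        sum(stats::dnbinom(y[idx], size = 1 / alpha, mu = exp(eta0[idx] + b),
                           log = TRUE))
      }
    }, numeric(1)) + stats::dnorm(bs, 0, sigma, log = TRUE)
    m <- max(s)
    total <- total + m + log(sum(exp(s - m)) * h)
  }
  total
}

# small fixture: region + sources reused across tests
tiny_region <- function(seed = 11) generate_region(4, 40, seed = seed)
tiny_sources <- function(region, seed = 12) {
  generate_sources(region, n_emitters = 20, n_wells = 200, seed = seed)
}

# one-patient event frame builder
ev <- function(event_type, code = NA, care_setting = NA,
               medication_class = NA) {
  data.frame(event_type = event_type, code = code,
             care_setting = care_setting,
             medication_class = medication_class, stringsAsFactors = FALSE)
}
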