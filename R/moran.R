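#' Row-standardized k-nearest-neighbor spatial weights
#'
#' Builds a sparse weight list: each point's k nearest neighbors (great
#' circle or planar distance, self excluded) receive weight 1/k.
#'
#' @param lat,lon Coordinates (degrees, or planar km).
#' @param k Number of neighbors (default 8; capped at n-1).
#' @param metric `"geodesic"` or `"planar"`.
#' @return List with integer vectors `i`, `j` and numeric `w` (triplet form),
#'   the point count `n`, and a `label`.
#' @export
knn_weights <- function(lat, lon, k = 8, metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  n <- length(lat)
  stopifnot(n >= 2, length(lon) == n)
  k <- min(k, n - 1)
  dfun <- dist_fun(metric)
  ii <- integer(0); jj <- integer(0)
  for (a in seq_len(n)) {
    d <- dfun(lat[a], lon[a], lat, lon)
    d[a] <- Inf
    nb <- order(d)[seq_len(k)]
    ii <- c(ii, rep(a, k)); jj <- c(jj, nb)
  }
  list(i = ii, j = jj, w = rep(1 / k, length(ii)), n = n,
       label = sprintf("knn%d_row_standardized", k))
}

#' Moran's I with a permutation null
#'
#' Global spatial autocorrelation statistic
#' I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with expectation -1/(n-1) under the permutation null. The p-value comes
#' from random permutations of the values across locations.
#'
#' @param values Numeric vector (must not be constant).
#' @param lat,lon Coordinates; ignored when `weights` is supplied.
#' @param weights Optional weight list as from [knn_weights()].
#' @param k Neighbors for the default weight scheme.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation draw.
#' @param alternative `"greater"` (positive autocorrelation, default) or
#'   `"two.sided"`.
#' @param metric Distance metric for the default weights.
#' @return Object of class `moran_result`: `I`, `expected_I` (-1/(n-1)),
#'   `p_perm` in (0, 1], `n_perm`, `weight_scheme`, and the permutation
#'   statistics `perm_I`.
#' @export
morans_i <- function(values, lat = NULL, lon = NULL, weights = NULL, k = 8,
                     n_perm = 999, seed = 1,
                     alternative = c("greater", "two.sided"),
                     metric = c("geodesic", "planar")) {
  alternative <- match.arg(alternative)
  metric <- match.arg(metric)
  n <- length(values)
  if (n < 3) stop("need n >= 3")
  if (length(unique(values)) < 2)
    stop("Moran's I is undefined for constant values")
  if (is.null(weights)) {
    if (is.null(lat) || is.null(lon))
      stop("supply coordinates or a weight list")
    weights <- knn_weights(lat, lon, k = k, metric = metric)
  }
  stopifnot(weights$n == n)
  W <- sum(weights$w)
  stat <- function(x) {
    z <- x - mean(x)
    (n / W) * sum(weights$w * z[weights$i] * z[weights$j]) / sum(z^2)
  }
  I_obs <- stat(values)
  local_seed(seed)
  perm_I <- vapply(seq_len(n_perm), function(p) stat(sample(values)),
                   numeric(1))
  p_perm <- switch(alternative,
    greater = (1 + sum(perm_I >= I_obs)) / (n_perm + 1),
    two.sided = {
      e <- -1 / (n - 1)
      (1 + sum(abs(perm_I - e) >= abs(I_obs - e))) / (n_perm + 1)
    })
  structure(list(I = I_obs, expected_I = -1 / (n - 1), p_perm = p_perm,
                 n_perm = n_perm, weight_scheme = weights$label,
                 perm_I = perm_I),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), p_perm = %.4f (%d perms, %s)\n",
              x$I, x$expected_I, x$p_perm, x$n_perm, x$weight_scheme))
  invisible(x)
}

#' Spatial-autocorrelation diagnostic for a fitted model
#'
#' Computes deviance residuals of the fit and tests them for residual
#' spatial autocorrelation at the retained residence coordinates with
#' [morans_i()]. With more than `max_n` observations a seeded subsample is
#' used to keep the distance work bounded.
#'
#' @param fit A `migrenv_fit`.
#' @param data The data frame the model was fitted to (for coordinates).
#' @param max_n Subsample cap (default 1500).
#' @inheritParams morans_i
#' @return A `moran_result`.
#' @export
moran_diagnostic <- function(fit, data, k = 8, n_perm = 999, seed = 1,
                             max_n = 1500) {
  r <- stats::residuals(fit, type = "deviance")
  rows <- fit$kept_rows
  lat <- data$lat[rows]; lon <- data$lon[rows]
  if (length(r) > max_n) {
    local_seed(seed + 1)
    idx <- sample.int(length(r), max_n)
    r <- r[idx]; lat <- lat[idx]; lon <- lon[idx]
  }
  morans_i(r, lat, lon, k = k, n_perm = n_perm, seed = seed)
}
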