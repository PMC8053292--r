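#' Penalized-spline exposure-response check
#'
#' Fits the exposure with a cubic P-spline basis (default 8 basis functions,
#' second-difference penalty) inside a generalized additive mixed model with
#' the county intercept as a Gaussian random-effect smooth, alongside the
#' same model with a linear exposure term. The smoothing parameter is chosen
#' by approximate marginal likelihood (`method = "ML"` in \pkg{mgcv}).
#' Reports the effective degrees of freedom of the exposure smooth, a
#' linear-vs-spline deviance comparison, and the fitted exposure-response
#' curve on a grid (for monotonicity checks).
#'
#' @inheritParams fit_glmm
#' @param k Spline basis dimension (default 8).
#' @param sp Optional fixed smoothing parameter for the exposure smooth
#'   (e.g. a very large value forces the fit back to the linear model).
#' @param grid_n Number of grid points for the reported fitted curve.
#' @return List of class `spline_fit`: `gam` (the mgcv fit), `edf`
#'   (effective df of the exposure smooth), `deviance_spline`,
#'   `deviance_linear`, `deviance_reduction`, `curve` (data frame `x`,
#'   `fit`, `se`), `nonmonotone` (logical: fitted curve changes direction),
#'   and the linear-fit `gam_linear`.
#' @export
spline_exposure_fit <- function(spec, data, k = 8, sp = NULL, grid_n = 100) {
  stopifnot(inherits(spec, "model_spec"))
  x <- data[[spec$exposure]]
  if (length(unique(x[!is.na(x)])) < 20)
    stop("need >= 20 distinct exposure values for a spline fit")
  df <- data
  df$.y <- df[[spec$outcome]]
  if (is.logical(df$.y)) df$.y <- as.numeric(df$.y)
  df$.grp <- factor(df[[spec$group]])
  for (cl in spec$covariates) {
    if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  }
  fam <- if (spec$family == "logistic") stats::binomial() else mgcv::nb()
  cov_part <- if (length(spec$covariates))
    paste("+", paste(spec$covariates, collapse = " + ")) else ""
  off_part <- if (!is.null(spec$offset))
    sprintf("+ offset(log(%s))", spec$offset) else ""
  re_part <- if (nlevels(df$.grp) >= 2) '+ s(.grp, bs = "re")' else ""
  f_spline <- stats::as.formula(sprintf(
    '.y ~ s(%s, bs = "ps", k = %d, m = c(2, 2)) %s %s %s',
    spec$exposure, k, cov_part, off_part, re_part))
  f_linear <- stats::as.formula(sprintf(
    ".y ~ %s %s %s %s", spec$exposure, cov_part, off_part, re_part))
  sp_arg <- if (is.null(sp)) NULL else
    c(sp, rep(-1, if (re_part == "") 0 else 1))
  fit_s <- mgcv::gam(f_spline, family = fam, data = df, method = "ML",
                     sp = sp_arg)
  fit_l <- mgcv::gam(f_linear, family = fam, data = df, method = "ML")
  sm_label <- paste0("s(", spec$exposure, ")")
  edf_all <- summary(fit_s)$s.table
  edf <- edf_all[rownames(edf_all) == sm_label, "edf"][1]

  xg <- seq(min(x, na.rm = TRUE), max(x, na.rm = TRUE), length.out = grid_n)
  newd <- df[rep(1, grid_n), , drop = FALSE]
  newd[[spec$exposure]] <- xg
  pr <- mgcv::predict.gam(fit_s, newdata = newd, type = "terms",
                          terms = sm_label, se.fit = TRUE)
  curve <- data.frame(x = xg, fit = drop(pr$fit), se = drop(pr$se.fit))
  d <- diff(curve$fit)
  nonmono <- any(d > 1e-8) && any(d < -1e-8)
  structure(list(
    gam = fit_s, gam_linear = fit_l, edf = edf,
    deviance_spline = stats::deviance(fit_s),
    deviance_linear = stats::deviance(fit_l),
    deviance_reduction = stats::deviance(fit_l) - stats::deviance(fit_s),
    curve = curve, nonmonotone = nonmono
  ), class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf(
    "P-spline exposure fit: edf = %.2f, deviance linear-spline = %.3f, %s\n",
    x$edf, x$deviance_reduction,
    if (x$nonmonotone) "non-monotone" else "monotone"))
  invisible(x)
}
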