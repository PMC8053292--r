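#' Specify a random-intercept regression model
#'
#' Describes one model of the analysis grid: a logistic or NB2 negative
#' binomial regression of an outcome on one exposure term plus an adjustment
#' set, with a county-level random intercept integrated out by adaptive
#' Gauss-Hermite quadrature.
#'
#' @param outcome Name of the outcome column (0/1 or logical for logistic,
#'   nonnegative counts for negbin).
#' @param exposure Name of the exposure column (already on its rescaled
#'   reporting unit for continuous exposures).
#' @param family `"logistic"` or `"negbin"` (NB2, variance mu + alpha mu^2).
#' @param covariates Character vector of adjustment columns. Character
#'   columns are treated as factors reference-coded against the first level
#'   in lexicographic order.
#' @param group Grouping column for the random intercept (default
#'   `"county_id"`).
#' @param offset Column whose log is the model offset (negbin only;
#'   typically `"person_years"`). `NULL` for none.
#' @param exposure_form `"continuous"`, `"binary"` or `"spline"` (the latter
#'   is handled by [spline_exposure_fit()]).
#' @param nAGQ Number of quadrature points (default 15).
#' @param scale_label Free-text label for the reporting unit of the exposure.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome, exposure, family = c("logistic", "negbin"),
                       covariates = character(0), group = "county_id",
                       offset = NULL,
                       exposure_form = c("continuous", "binary", "spline"),
                       nAGQ = 15, scale_label = "") {
  family <- match.arg(family)
  exposure_form <- match.arg(exposure_form)
  if (!is.null(offset) && family != "negbin")
    stop("an offset is only supported for negbin models")
  structure(list(outcome = outcome, exposure = exposure, family = family,
                 covariates = covariates, group = group, offset = offset,
                 exposure_form = exposure_form, nAGQ = nAGQ,
                 scale_label = scale_label),
            class = "model_spec")
}

# Observation-level loglik/score/curvature closures for one evaluation.
# For NB2 the y-and-dispersion-only normalizing constant is computed once
# and reused across the quadrature passes.
obs_family <- function(family, y, alpha) {
  if (family == "logistic") {
    list(
      # y*eta - log(1 + e^eta), with log(1+e^eta) = max(eta,0) + log1p(e^-|eta|)
      ll = function(eta) y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))),
      score = function(eta) y - stats::plogis(eta),
      curv = function(eta) {
        p <- stats::plogis(eta)
        -p * (1 - p)
      }
    )
  } else {
    k <- 1 / alpha
    C <- lgamma(y + k) - lgamma(k) - lfactorial(y) + k * log(k)
    list(
      ll = function(eta) C + y * eta - (y + k) * log(exp(eta) + k),
      score = function(eta) {
        mu <- exp(eta)
        y - (y + k) * mu / (mu + k)
      },
      curv = function(eta) {
        mu <- exp(eta)
        -(y + k) * k * mu / (mu + k)^2
      }
    )
  }
}

# marginal log-likelihood by adaptive Gauss-Hermite quadrature.
# Observations must be ordered by group; `group_sum` sums an
# observation-level vector within groups (cumsum trick), gi expands group
# vectors to observations.
agq_loglik <- function(y, eta0, gi, G, sigma, alpha, family, gh, group_sum,
                       b_start = NULL, return_modes = FALSE) {
  fam <- obs_family(family, y, alpha)
  if (sigma <= 0) {
    ll <- sum(fam$ll(eta0))
    if (return_modes) return(list(loglik = ll, modes = numeric(G),
                                  tau = rep(NA_real_, G)))
    return(ll)
  }
  b <- if (is.null(b_start)) numeric(G) else b_start
  inv_s2 <- 1 / sigma^2
  # Newton iterations for the conditional modes (concave objective)
  for (it in 1:60) {
    eta <- eta0 + b[gi]
    U <- group_sum(fam$score(eta)) - b * inv_s2
    H <- group_sum(fam$curv(eta)) - inv_s2
    step <- pmin(pmax(U / H, -4), 4)
    b <- b - step
    if (max(abs(U)) < 1e-8) break
  }
  H <- group_sum(fam$curv(eta0 + b[gi])) - inv_s2
  tau <- 1 / sqrt(-H)
  K <- length(gh$nodes)
  lg <- matrix(0, G, K)
  for (k in seq_len(K)) {
    bk <- b + sqrt(2) * tau * gh$nodes[k]
    s <- group_sum(fam$ll(eta0 + bk[gi])) +
      stats::dnorm(bk, 0, sigma, log = TRUE)
    lg[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + s
  }
  m <- apply(lg, 1, max)
  ll_g <- m + log(rowSums(exp(lg - m))) + log(sqrt(2) * tau)
  ll <- sum(ll_g)
  if (return_modes) return(list(loglik = ll, modes = b, tau = tau))
  ll
}

#' Fit a random-intercept GLMM by adaptive Gauss-Hermite quadrature
#'
#' Maximizes the marginal likelihood, integrating a single Gaussian random
#' intercept per group by AGQ centered at each group's conditional mode with
#' mode curvature scaling. The NB2 dispersion (negbin) is estimated jointly.
#' Wald confidence intervals come from the inverse of the numerically
#' differentiated observed information. The convergence flag is honest:
#' optimizer success plus a positive-definite information matrix; suspected
#' separation (a coefficient beyond +/-15) also marks the fit as not
#' converged.
#'
#' @param spec A [model_spec()].
#' @param data Data frame holding all referenced columns.
#' @param sigma_fixed Optional fixed value for the random-intercept SD; use
#'   `0` to reduce the model to an ordinary GLM (no integration).
#' @param ci_level Confidence level for the Wald interval (default 0.95).
#' @return Object of class `migrenv_fit` with elements `beta`, `se`, `vcov`,
#'   `sigma_u`, `alpha` (negbin), `loglik`, `converged`,
#'   `effect_estimate` (OR/RR with CI on the rescaled-unit scale), `modes`
#'   (empirical-Bayes group intercepts), `negloglik` (the objective as a
#'   function of the full parameter vector, for verification against
#'   independent integration), and bookkeeping fields.
#' @export
fit_glmm <- function(spec, data, sigma_fixed = NULL, ci_level = 0.95) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$outcome, spec$exposure, spec$covariates,
            spec$group, spec$offset)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[, unique(need), drop = FALSE]
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]

  y <- df[[spec$outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (spec$family == "logistic" && !all(y %in% c(0, 1)))
    stop("logistic outcome must be binary")
  if (spec$family == "negbin" && any(y < 0 | y != floor(y)))
    stop("negbin outcome must be nonnegative counts")

  rhs <- c(spec$exposure, spec$covariates)
  mm_df <- df[, rhs, drop = FALSE]
  for (cl in names(mm_df)) {
    if (is.character(mm_df[[cl]])) mm_df[[cl]] <- factor(mm_df[[cl]])
    if (is.logical(mm_df[[cl]])) mm_df[[cl]] <- as.numeric(mm_df[[cl]])
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(rhs, collapse = " + "))), mm_df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  off <- if (is.null(spec$offset)) rep(0, nrow(df)) else log(df[[spec$offset]])
  g <- factor(df[[spec$group]])
  G <- nlevels(g)
  if (is.null(sigma_fixed) && G < 2)
    stop("need >= 2 groups for a random intercept")
  gi <- as.integer(g)
  # order by group once: group sums become a cumsum + two subsets
  ord <- order(gi)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  off <- off[ord]
  gi <- gi[ord]
  kept_rows <- which(keep)[ord]
  ends <- cumsum(tabulate(gi, nbins = G))
  group_sum <- function(x) {
    cs <- cumsum(x)
    cs[ends] - c(0, cs[ends[-G]])
  }
  gh <- gauss_hermite(spec$nAGQ)
  p <- ncol(X)
  est_sigma <- is.null(sigma_fixed)
  est_alpha <- spec$family == "negbin"

  # start values from the fixed-effects GLM
  start_fit <- if (spec$family == "logistic") {
    stats::glm.fit(X, y, family = stats::binomial())
  } else {
    stats::glm.fit(X, y, family = stats::poisson(), offset = off)
  }
  beta0 <- start_fit$coefficients
  beta0[!is.finite(beta0)] <- 0
  par0 <- beta0
  if (est_sigma) par0 <- c(par0, log_sigma = log(0.3))
  if (est_alpha) par0 <- c(par0, log_alpha = log(0.5))

  env <- new.env()
  env$b <- numeric(G)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    sigma <- if (est_sigma) exp(par[p + 1]) else sigma_fixed
    alpha <- if (est_alpha) exp(par[length(par)]) else NA_real_
    eta0 <- drop(X %*% beta) + off
    res <- agq_loglik(y, eta0, gi, G, sigma, alpha, spec$family, gh,
                      group_sum, b_start = env$b, return_modes = TRUE)
    if (sigma > 0) env$b <- res$modes
    ll <- res$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lower <- c(rep(-Inf, p), if (est_sigma) -8, if (est_alpha) -8)
  upper <- c(rep(Inf, p), if (est_sigma) 3, if (est_alpha) 5)
  opt <- stats::nlminb(par0, nll, lower = lower, upper = upper,
                       control = list(eval.max = 2000, iter.max = 1000))
  # polish with a central-difference gradient: nlminb's internal forward
  # differences leave ~1e-5 noise in the optimum
  grad <- function(par) {
    h <- 1e-5 * (1 + abs(par))
    vapply(seq_along(par), function(j) {
      e <- replace(numeric(length(par)), j, h[j])
      (nll(par + e) - nll(par - e)) / (2 * h[j])
    }, numeric(1))
  }
  opt2 <- stats::nlminb(opt$par, nll, gradient = grad, lower = lower,
                        upper = upper, control = list(iter.max = 100))
  if (opt2$objective <= opt$objective) opt <- opt2
  par_hat <- opt$par
  hess <- tryCatch(stats::optimHess(par_hat, nll), error = function(e) NULL)
  vcov_all <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  ok_vcov <- !is.null(vcov_all) && all(is.finite(diag(vcov_all))) &&
    all(diag(vcov_all)[seq_len(p)] > 0)
  beta <- par_hat[seq_len(p)]
  names(beta) <- colnames(X)
  # separation heuristic on the standardized scale: a one-SD change in any
  # column shifting the log odds by > 12 signals a degenerate fit
  sdx <- apply(X, 2, stats::sd)
  std_eff <- abs(beta[-1]) * sdx[-1]
  separated <- p > 1 && length(std_eff) && any(std_eff > 12)
  converged <- (opt$convergence == 0) && ok_vcov && !separated
  se <- if (ok_vcov) sqrt(diag(vcov_all)[seq_len(p)]) else rep(NA_real_, p)
  names(se) <- colnames(X)
  sigma_u <- if (est_sigma) unname(exp(par_hat[p + 1])) else sigma_fixed
  alpha <- if (est_alpha) unname(exp(par_hat[length(par_hat)])) else NA_real_

  # exposure effect on the exponentiated scale
  expo_cols <- grep(paste0("^", expo_regex(spec$exposure)), colnames(X),
                    value = TRUE)
  expo_col <- if (spec$exposure %in% colnames(X)) spec$exposure else
    expo_cols[1]
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  eff <- if (!is.na(expo_col) && length(expo_col)) {
    b1 <- beta[[expo_col]]
    s1 <- se[[expo_col]]
    list(term = expo_col,
         estimate = exp(b1), lower = exp(b1 - zq * s1),
         upper = exp(b1 + zq * s1),
         log_estimate = b1, se = s1,
         measure = if (spec$family == "logistic") "OR" else "RR",
         scale_label = spec$scale_label)
  } else NULL

  # empirical-Bayes modes at the optimum, for residuals/diagnostics
  eta0_hat <- drop(X %*% beta) + off
  final <- agq_loglik(y, eta0_hat, gi, G, sigma_u, alpha, spec$family, gh,
                      group_sum, b_start = env$b, return_modes = TRUE)
  modes <- final$modes
  names(modes) <- levels(g)

  structure(list(
    spec = spec, beta = beta, se = se,
    vcov = if (ok_vcov) vcov_all[seq_len(p), seq_len(p), drop = FALSE] else NULL,
    sigma_u = sigma_u, alpha = alpha, loglik = -opt$objective,
    converged = converged, effect_estimate = eff,
    modes = modes, n = nrow(df), n_groups = G,
    y = y, eta_hat = eta0_hat + modes[gi], family = spec$family,
    kept_rows = kept_rows,
    negloglik = nll
  ), class = "migrenv_fit")
}

expo_regex <- function(x) gsub("([][(){}.^$*+?\\\\|])", "\\\\\\1", x)

#' @export
print.migrenv_fit <- function(x, ...) {
  cat(sprintf("Random-intercept %s model: %s ~ %s (+%d covariates)\n",
              x$spec$family, x$spec$outcome, x$spec$exposure,
              length(x$spec$covariates)))
  cat(sprintf("n = %d, groups = %d, sigma_u = %.4f%s, loglik = %.2f, %s\n",
              x$n, x$n_groups, x$sigma_u,
              if (!is.na(x$alpha)) sprintf(", alpha = %.4f", x$alpha) else "",
              x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (!is.null(x$effect_estimate)) {
    e <- x$effect_estimate
    cat(sprintf("%s = %.4f (95%% CI %.4f, %.4f) %s\n",
                e$measure, e$estimate, e$lower, e$upper, e$scale_label))
  }
  invisible(x)
}

#' Deviance (or response) residuals of a fitted GLMM
#'
#' Residuals are computed at the conditional fit, i.e. with the
#' empirical-Bayes group intercepts plugged in.
#'
#' @param object A `migrenv_fit`.
#' @param type `"deviance"` or `"response"`.
#' @param ... Unused.
#' @return Numeric vector of residuals (one per retained row).
#' @export
residuals.migrenv_fit <- function(object, type = c("deviance", "response"),
                                  ...) {
  type <- match.arg(type)
  y <- object$y
  eta <- object$eta_hat
  if (object$family == "logistic") {
    mu <- stats::plogis(eta)
    if (type == "response") return(y - mu)
    d <- -2 * (y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    sign(y - mu) * sqrt(pmax(d, 0))
  } else {
    mu <- exp(eta)
    if (type == "response") return(y - mu)
    k <- 1 / object$alpha
    llsat <- stats::dnbinom(y, size = k, mu = pmax(y, 1e-12), log = TRUE)
    llmod <- stats::dnbinom(y, size = k, mu = mu, log = TRUE)
    sign(y - mu) * sqrt(pmax(2 * (llsat - llmod), 0))
  }
}

#' Tabulate exposure effects from a list of fits
#'
#' One row per fitted model: exposure, outcome, family, the exponentiated
#' effect per rescaled unit with its Wald interval, the scale label, and the
#' convergence flag. Values survive a round trip through the delimited output
#' format at 6 significant digits.
#'
#' @param fits List of `migrenv_fit` objects (may be empty).
#' @param labels Optional character vector of model labels.
#' @return Data frame with columns `label`, `exposure`, `outcome`, `family`,
#'   `measure`, `estimate`, `lower`, `upper`, `scale`, `sigma_u`,
#'   `converged`.
#' @export
effect_table <- function(fits, labels = NULL) {
  cols <- c("label", "exposure", "outcome", "family", "measure",
            "estimate", "lower", "upper", "scale", "sigma_u", "converged")
  if (length(fits) == 0) {
    out <- data.frame(label = character(), exposure = character(),
                      outcome = character(), family = character(),
                      measure = character(), estimate = numeric(),
                      lower = numeric(), upper = numeric(),
                      scale = character(), sigma_u = numeric(),
                      converged = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(labels)) labels <- vapply(fits, function(f)
    paste(f$spec$outcome, f$spec$exposure, sep = "~"), character(1))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    e <- f$effect_estimate
    data.frame(label = labels[i], exposure = f$spec$exposure,
               outcome = f$spec$outcome, family = f$spec$family,
               measure = if (is.null(e)) NA_character_ else e$measure,
               estimate = if (is.null(e)) NA_real_ else e$estimate,
               lower = if (is.null(e)) NA_real_ else e$lower,
               upper = if (is.null(e)) NA_real_ else e$upper,
               scale = f$spec$scale_label,
               sigma_u = f$sigma_u, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
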