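test_that("sigma = 0 logistic fit reproduces the 2x2 cross-product OR", {
  d <- data.frame(
    y = c(rep(1, 50), rep(0, 50), rep(1, 25), rep(0, 75)),
    x = c(rep(1, 100), rep(0, 100)),
    county_id = rep(c("a", "b"), 100))
  f <- fit_glmm(model_spec("y", "x", "logistic"), d, sigma_fixed = 0)
  expect_true(f$converged)
  expect_equal(f$effect_estimate$estimate, (50 * 75) / (50 * 25),
               tolerance = 1e-6)
  # matches ordinary logistic regression
  g <- stats::glm(y ~ x, stats::binomial, d)
  expect_equal(unname(f$beta), unname(stats::coef(g)), tolerance = 1e-6)
})

test_that("sigma = 0 negbin fit matches fixed-theta GLM coefficients", {
  set.seed(1)
  n <- 2000
  x <- rnorm(n)
  py <- runif(n, 0.5, 3)
  y <- rnbinom(n, size = 2, mu = exp(0.3 + 0.4 * x + log(py)))
  d <- data.frame(y = y, x = x, person_years = py,
                  county_id = rep(c("a", "b"), n / 2))
  f <- fit_glmm(model_spec("y", "x", "negbin", offset = "person_years"), d,
                sigma_fixed = 0)
  expect_true(f$converged)
  # at the fitted dispersion, IRLS with fixed theta is an exact oracle
  g <- stats::glm(y ~ x + offset(log(py)),
                  family = MASS::negative.binomial(theta = 1 / f$alpha),
                  control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(f$beta), unname(stats::coef(g)), tolerance = 1e-6)
  # and the jointly estimated dispersion agrees with glm.nb
  gn <- MASS::glm.nb(y ~ x + offset(log(py)))
  expect_equal(f$alpha, 1 / gn$theta, tolerance = 1e-3)
})

test_that("negbin collapses to Poisson as dispersion vanishes", {
  set.seed(2)
  n <- 3000
  x <- rnorm(n)
  y <- rpois(n, exp(0.5 + 0.3 * x))
  d <- data.frame(y = y, x = x, county_id = rep(c("a", "b"), n / 2))
  f <- fit_glmm(model_spec("y", "x", "negbin"), d, sigma_fixed = 0)
  g <- stats::glm(y ~ x, stats::poisson, d)
  expect_lt(f$alpha, 0.02)
  expect_equal(unname(f$beta), unname(stats::coef(g)), tolerance = 1e-3)
})

test_that("AGQ marginal likelihood matches dense numerical integration", {
  set.seed(3)
  n <- 400
  G <- 8
  g <- sample(G, n, replace = TRUE)
  x <- rnorm(n)
  b_true <- rnorm(G, 0, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * x + b_true[g]))
  d <- data.frame(y = y, x = x, county_id = letters[g])
  f <- fit_glmm(model_spec("y", "x", "logistic"), d)
  # at the optimum and at two displaced parameter points
  for (shift in c(0, 0.15, -0.2)) {
    par <- c(f$beta + shift, log(f$sigma_u * exp(shift / 2)))
    sigma <- exp(par[3])
    ll_agq <- -f$negloglik(par)
    eta0 <- par[1] + par[2] * d$x
    ll_dense <- dense_loglik(d$y, eta0, d$county_id, sigma)
    expect_equal(ll_agq, ll_dense, tolerance = 1e-6)
  }
  # negbin family too
  set.seed(4)
  yc <- rnbinom(n, size = 1.5, mu = exp(0.2 + 0.3 * x + b_true[g]))
  dc <- data.frame(y = yc, x = x, county_id = letters[g])
  fc <- fit_glmm(model_spec("y", "x", "negbin"), dc)
  par <- c(fc$beta, log(fc$sigma_u), log(fc$alpha))
  ll_agq <- -fc$negloglik(par)
  eta0 <- par[1] + par[2] * dc$x
  ll_dense <- dense_loglik(dc$y, eta0, dc$county_id, fc$sigma_u,
                           family = "negbin", alpha = fc$alpha)
  expect_equal(ll_agq, ll_dense, tolerance = 1e-6)
})

test_that("the fitter recovers a known exposure effect from generated data", {
  r <- generate_region(10, 100, seed = 51)
  tr <- true_model(exposure_betas = c(no2 = log(1.5)), county_sigma = 0.3,
                   seed = 52)
  co <- generate_cohort(r, source_set(), 6000, tr, events = FALSE)
  e <- rescale_exposures(compute_exposures(co$patients, r, source_set()))
  d <- merge(co$patients, e, by = "patient_id")
  d$is_case <- d$latent_case
  f <- fit_glmm(model_spec("is_case", "no2", "logistic"), d)
  expect_true(f$converged)
  expect_gt(f$effect_estimate$upper, 1.5)
  expect_lt(f$effect_estimate$lower, 1.5)
})

test_that("shifting a covariate by a constant moves only the intercept", {
  set.seed(9)
  n <- 1500
  g <- sample(6, n, replace = TRUE)
  x <- rnorm(n)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.5 * x + 0.3 * z + rnorm(6, 0, 0.3)[g]))
  d <- data.frame(y = y, x = x, z = z, county_id = letters[g])
  f1 <- fit_glmm(model_spec("y", "x", "logistic", covariates = "z"), d)
  d2 <- d
  d2$z <- d$z + 10
  f2 <- fit_glmm(model_spec("y", "x", "logistic", covariates = "z"), d2)
  expect_equal(f1$beta[["x"]], f2$beta[["x"]], tolerance = 1e-3)
  expect_equal(f1$beta[["z"]], f2$beta[["z"]], tolerance = 1e-3)
  expect_equal(f1$beta[["(Intercept)"]] ,
               f2$beta[["(Intercept)"]] + 10 * f2$beta[["z"]],
               tolerance = 1e-2)
})

test_that("degenerate designs fail loudly and honestly", {
  set.seed(10)
  d <- data.frame(y = rbinom(100, 1, 0.4), x = rnorm(100),
                  county_id = rep(c("a", "b"), 50))
  d$x2 <- 2 * d$x
  expect_error(
    fit_glmm(model_spec("y", "x", "logistic", covariates = "x2"), d),
    "collinear.*x2")
  # perfect separation -> flagged, not silently reported as fine
  ds <- data.frame(y = rep(c(0, 1), each = 50),
                   x = rep(c(-1, 1), each = 50) + runif(100, 0, 0.1),
                   county_id = rep(c("a", "b"), 50))
  fs <- fit_glmm(model_spec("y", "x", "logistic"), ds, sigma_fixed = 0)
  expect_false(fs$converged)
  # missing column
  expect_error(fit_glmm(model_spec("y", "nope", "logistic"), d),
               "missing columns")
  # offset only for negbin
  expect_error(model_spec("y", "x", "logistic", offset = "person_years"),
               "offset")
})

test_that("effect tables report exponentiated Wald intervals losslessly", {
  set.seed(11)
  n <- 800
  g <- sample(4, n, replace = TRUE)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * x + rnorm(4, 0, 0.2)[g]))
  d <- data.frame(y = y, x = x, county_id = letters[g])
  f <- fit_glmm(model_spec("y", "x", "logistic", scale_label = "per unit"), d)
  tab <- effect_table(list(f))
  expect_equal(nrow(tab), 1)
  e <- f$effect_estimate
  expect_equal(tab$estimate, exp(e$log_estimate))
  expect_equal(tab$lower, exp(e$log_estimate - qnorm(0.975) * e$se))
  expect_equal(tab$upper, exp(e$log_estimate + qnorm(0.975) * e$se))
  expect_true(tab$lower <= tab$estimate && tab$estimate <= tab$upper)
  # null effect reports OR 1 exactly when beta is zero
  f0 <- f
  f0$effect_estimate$log_estimate <- 0
  f0$effect_estimate$estimate <- exp(0)
  expect_equal(effect_table(list(f0))$estimate, 1)
  # empty list -> empty table with the full header
  empty <- effect_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("exposure", "outcome", "estimate", "lower", "upper") %in%
                    names(empty)))
  # delimited round trip at 6 significant digits
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(signif(back$estimate, 6), signif(tab$estimate, 6))
  expect_equal(signif(back$lower, 6), signif(tab$lower, 6))
})
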