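# Small two-survey dataset with hand-picked parameter values used to compare
# the compiled joint density against the plain-R reference computation.
joint_check_case <- function() {
  set.seed(31)
  hauls <- tibble::tibble(
    survey = rep(c("IBTS", "CTS"), 15),
    year = rep(2018:2020, each = 10),
    x_km = runif(30, 0, 80), y_km = runif(30, 0, 40),
    density_per_km2 = ifelse(runif(30) < 0.4, 0, rgamma(30, 1, 1 / 40))
  )
  spec <- delta_spec(binomial = "spatial", gamma = "st_ar1",
                     anisotropy = TRUE, n_knots = 8L)
  prep <- litterindex:::prepare_delta_data(hauls, spec)
  K <- nrow(prep$knots)
  set.seed(32)
  pars <- list(
    beta1 = c(-0.3, 0.1, -0.2, 0.15), beta2 = c(3, 3.2, 2.8, -0.1),
    log_sigma = log(c(0.5, 0.7)), log_range = log(c(20, 30)),
    angle = c(0.4, 0.4), log_ratio = log(c(1.5, 2)),
    trans_rho = c(0, -log(1 / ((0.6 + 1) / 2) - 1)), # rho2 = 0.6
    log_phi = log(1.2),
    omega = cbind(rnorm(K, 0, 0.4), rep(0, K)),
    delta1 = array(0, c(K, 3)), delta2 = array(rnorm(K * 3, 0, 0.5), c(K, 3))
  )
  params_r <- list(
    beta1 = pars$beta1, beta2 = pars$beta2, sigma = c(0.5, 0.7),
    range = c(20, 30), angle = c(0.4, 0.4), ratio = c(1.5, 2),
    rho = c(0, 0.6), phi = 1.2
  )
  fields_r <- list(omega = pars$omega, delta2 = pars$delta2)
  list(hauls = hauls, spec = spec, prep = prep, pars = pars,
       params_r = params_r, fields_r = fields_r)
}

test_that("compiled joint density equals the plain-R reference computation", {
  cc <- joint_check_case()
  inp <- litterindex:::build_tmb_inputs(cc$prep, cc$spec, pars = cc$pars)
  obj <- TMB::MakeADFun(inp$data, inp$pars, map = inp$map,
                        DLL = "litterindex", silent = TRUE)
  nll_tmb <- obj$fn(obj$par)
  nll_r <- joint_neg_log_density(cc$hauls, cc$spec, cc$params_r, cc$fields_r)
  expect_equal(nll_tmb, nll_r, tolerance = 1e-8)
})

test_that("likelihood is invariant to the anisotropy angle when ratio = 1", {
  cc <- joint_check_case()
  pars <- cc$pars
  pars$log_ratio <- c(0, 0)
  inp <- litterindex:::build_tmb_inputs(cc$prep, cc$spec, pars = pars)
  obj <- TMB::MakeADFun(inp$data, inp$pars, map = inp$map,
                        DLL = "litterindex", silent = TRUE)
  gr <- obj$gr(obj$par)
  expect_lt(max(abs(gr[names(obj$par) == "angle"])), 1e-6)
  # and the value itself does not move with the angle
  pars2 <- pars
  pars2$angle <- c(1.3, -0.7)
  inp2 <- litterindex:::build_tmb_inputs(cc$prep, cc$spec, pars = pars2)
  obj2 <- TMB::MakeADFun(inp2$data, inp2$pars, map = inp2$map,
                         DLL = "litterindex", silent = TRUE)
  expect_equal(obj$fn(obj$par), obj2$fn(obj2$par), tolerance = 1e-10)
})

test_that("with fields disabled the fit reduces to two GLMs", {
  h <- test_glm_hauls()
  f <- test_glm_fit()
  pres <- h$density_per_km2 > 0
  yr <- factor(h$year)
  gb <- stats::glm(pres ~ 0 + yr, family = stats::binomial("cloglog"))
  expect_lt(max(abs(f$parlist$beta1 - unname(stats::coef(gb)))), 1e-3)

  # the Gamma component picks up the positive-rate GLM after the
  # Poisson-link reparameterization log r = eta1 + eta2 - log p
  gg <- stats::glm(density_per_km2 ~ 0 + yr, subset = pres,
                   family = stats::Gamma("log"), data = h)
  p_hat <- 1 - exp(-exp(stats::coef(gb)))
  beta2_oracle <- stats::coef(gg) - stats::coef(gb) + log(p_hat)
  expect_lt(max(abs(f$parlist$beta2 - unname(beta2_oracle))), 1e-3)
  expect_true(f$diagnostics$pd_hessian)
  expect_lt(f$diagnostics$max_gradient, 1e-3)
})

test_that("a single positive haul drives its Gamma mean to the observation", {
  hauls <- tibble::tibble(
    survey = "IBTS", year = rep(2019:2020, each = 2),
    x_km = rep(c(0, 30), 2), y_km = rep(c(0, 20), 2),
    density_per_km2 = c(0, 25.5, 3, 0)
  )
  spec <- delta_spec(binomial = "none", gamma = "none")
  base <- list(beta1 = c(-0.2, -0.2), beta2 = c(3, 1), sigma = c(0, 0),
               range = c(1, 1), rho = c(0, 0), phi = 1.7)
  nll_b2 <- function(b2) {
    p <- base; p$beta2[1] <- b2
    joint_neg_log_density(hauls, spec, p)
  }
  opt <- stats::optimize(Vectorize(nll_b2), c(-5, 15))
  pl <- poisson_link(-0.2, opt$minimum)
  expect_equal(pl$r, 25.5, tolerance = 1e-4)
})

test_that("duplicating every haul keeps estimates and halves the variance", {
  h <- test_glm_hauls()
  f1 <- test_glm_fit()
  f2 <- fit_delta_glmm(dplyr::bind_rows(h, h),
                       delta_spec(binomial = "none", gamma = "none"))
  expect_lt(max(abs(f1$parlist$beta1 - f2$parlist$beta1)), 1e-3)
  expect_lt(max(abs(f1$parlist$beta2 - f2$parlist$beta2)), 1e-3)
  s1 <- summary(f1$sdr, "fixed")[, "Std. Error"]
  s2 <- summary(f2$sdr, "fixed")[, "Std. Error"]
  expect_equal(unname(s2^2 / s1^2), rep(0.5, length(s1)), tolerance = 0.1)
})

test_that("predictions obey the Poisson-link identity and field switches", {
  f <- test_field_fit()
  pr <- predict(f, include_fields = TRUE)
  expect_equal(pr$p * pr$r, exp(pr$eta1 + pr$eta2), tolerance = 1e-12)

  # fixed-effects-only predictions ignore location entirely
  nd <- tibble::tibble(year = 2018, survey = "IBTS",
                       x_km = c(0, 150), y_km = c(0, 90))
  pf <- predict(f, nd, include_fields = FALSE)
  expect_equal(pf$mean[1], pf$mean[2])

  # with fields on, the prediction is exp(X b + omega + delta) at the knot
  pw <- predict(f, nd, include_fields = TRUE)
  ki <- litterindex:::nearest_knot(f$knots, nd$x_km, nd$y_km)
  yi <- match(2018, f$years)
  expect_equal(pw$eta1,
               pf$eta1 + f$parlist$omega[ki, 1], tolerance = 1e-12)
  expect_equal(pw$eta2,
               pf$eta2 + f$parlist$delta2[ki, yi], tolerance = 1e-12)

  expect_error(predict(f, tibble::tibble(year = 1999)), "outside fitted")
  expect_error(predict(f, tibble::tibble(year = 2018, survey = "ROV")),
               "outside fitted")
})

test_that("simulated quantile residuals are uniform under the fitted model", {
  f <- test_glm_fit()
  qr <- quantile_residuals(f, n_sims = 300, seed = 21)
  expect_true(all(qr$residual > 0 & qr$residual < 1))
  expect_gt(stats::ks.test(qr$residual, "punif")$p.value, 0.01)

  # an impossible observation lands at the top of its simulated CDF
  f2 <- f
  f2$data$density_per_km2[1] <- 1e9
  qr2 <- quantile_residuals(f2, n_sims = 100, seed = 22)
  expect_gt(qr2$residual[1], 0.98)
  expect_warning(quantile_residuals(f, n_sims = 20, seed = 1), "coarse")
})

test_that("model selection tabulates delta-AIC on identical data only", {
  h <- test_glm_hauls()
  f_glm <- test_glm_fit()
  f_sp <- fit_delta_glmm(h, delta_spec(binomial = "none", gamma = "spatial",
                                       n_knots = 10))
  tab <- select_model(list(glm = f_glm, spatial = f_sp))
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(attr(tab, "best"), tab$model[1])
  expect_equal(sort(tab$aic), tab$aic)
  expect_equal(marginal_aic(f_glm), 2 * f_glm$npar - 2 * f_glm$logLik)
  expect_error(select_model(list(f_glm, test_field_fit())), "identical")
})

test_that("haul validation catches unusable inputs", {
  h <- test_glm_hauls()
  expect_error(fit_delta_glmm(dplyr::select(h, -year), delta_spec()), "year")
  expect_error(fit_delta_glmm(dplyr::mutate(h, density_per_km2 = -1),
                              delta_spec()), "negative")
  expect_error(
    fit_delta_glmm(dplyr::filter(h, year != 2018), delta_spec()),
    "2018"
  )
  expect_error(
    fit_delta_glmm(h, delta_spec(reference_survey = "CTS")), "reference"
  )
  # an all-zero survey is excluded from fitting, with a message
  uwtv <- tibble::tibble(survey = "UWTV", year = 2018, x_km = 1:5,
                         y_km = 1, density_per_km2 = 0)
  expect_message(
    f <- fit_delta_glmm(dplyr::bind_rows(h, uwtv),
                        delta_spec(binomial = "none", gamma = "none")),
    "UWTV"
  )
  expect_false("UWTV" %in% f$survey_levels)
})
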