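test_that("annual index is exp(beta1_y + beta2_y) with a valid interval", {
  f <- test_glm_fit()
  idx <- annual_index(f)
  expect_equal(idx$year, f$years)
  expect_equal(idx$estimate,
               unname(exp(f$parlist$beta1[f$year_cols] +
                            f$parlist$beta2[f$year_cols])),
               tolerance = 1e-10)
  expect_true(all(idx$lo < idx$estimate & idx$estimate < idx$hi))
  expect_true(all(idx$cv > 0))
  expect_equal(idx$cv, idx$se / idx$estimate, tolerance = 1e-12)
})

test_that("indices recover the generating year means (fields off)", {
  f <- test_glm_fit()
  idx <- annual_index(f)
  tru <- true_annual_index(glm_truth())
  # log-scale z-scores within 3 SE for every year
  z <- abs(log(idx$estimate) - log(tru$true_index)) / idx$cv
  expect_true(all(z < 3))
})

test_that("Wald and simulation-based index uncertainty agree", {
  f <- test_glm_fit()
  w <- annual_index(f, method = "wald")
  s <- annual_index(f, method = "sim", n_sims = 3000, seed = 8)
  expect_equal(w$estimate, s$estimate)
  expect_true(all(s$se / w$se > 0.7 & s$se / w$se < 1.4))
  expect_true(all(abs(log(s$lo / w$lo)) < 0.35))
})

test_that("weighted trend recovers exact lines and degenerate inputs error", {
  idx <- tibble::tibble(year = 2011:2015, estimate = 10 - 2 * (0:4), cv = 0.2)
  # an exactly linear input triggers the usual "perfect fit" lm warning
  tr <- suppressWarnings(weighted_trend(idx))
  expect_equal(tr$slope, -2, tolerance = 1e-12)
  expect_true(tr$conf_low < -2 && -2 < tr$conf_high)

  flat <- tibble::tibble(year = 2011:2015, estimate = 7, cv = c(1:5) / 10)
  expect_equal(suppressWarnings(weighted_trend(flat))$slope, 0,
               tolerance = 1e-12)

  expect_error(weighted_trend(idx[1:2, ]), "3 years")
  expect_error(weighted_trend(dplyr::mutate(idx, cv = 0)), "positive")
})

test_that("trend is scale-equivariant and order-invariant", {
  set.seed(12)
  idx <- tibble::tibble(year = 2012:2020,
                        estimate = exp(rnorm(9, 3, 0.4)),
                        cv = runif(9, 0.2, 0.5))
  t1 <- weighted_trend(idx)
  t7 <- weighted_trend(dplyr::mutate(idx, estimate = estimate * 7))
  expect_equal(t7$slope, 7 * t1$slope, tolerance = 1e-10)
  expect_equal(t7$conf_low, 7 * t1$conf_low, tolerance = 1e-10)
  shuf <- weighted_trend(idx[sample(9), ])
  expect_equal(shuf$slope, t1$slope, tolerance = 1e-12)
  # inverse-CV^2 weighting is available and differs in general
  t2 <- weighted_trend(idx, weights = "inverse_cv2")
  expect_false(isTRUE(all.equal(t1$slope, t2$slope)))
})

test_that("trend interval covers a true decline at near-nominal rate", {
  set.seed(13)
  years <- 2012:2024
  true_est <- 60 - 2 * (years - 2012)
  hits <- 0
  for (r in 1:100) {
    se <- 0.15 * true_est
    est <- pmax(true_est + rnorm(13, 0, se), 1)
    idx <- tibble::tibble(year = years, estimate = est, cv = se / est)
    tr <- weighted_trend(idx)
    if (tr$conf_low <= -2 && -2 <= tr$conf_high) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
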