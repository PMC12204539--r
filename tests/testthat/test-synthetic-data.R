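test_that("layout respects footprints and yearly coverage", {
  tc <- truth_config(years = 2018:2020,
                     hauls_per_year = c(IBTS = 15L, CTS = 10L), seed = 2)
  lay <- gen_layout(tc)
  expect_equal(nrow(lay), 3 * 25)
  counts <- dplyr::count(lay, .data$year, .data$survey)
  expect_true(all(table(lay$year, lay$survey) > 0))
  expect_true(all(lay$y_km[lay$survey == "CTS"] <= tc$coastal_max_y))
  expect_true(all(lay$y_km[lay$survey == "IBTS"] >= tc$offshore_min_y))
  # zero overlap: no coastal haul inside the offshore box
  tc0 <- truth_config(years = 2018:2019, coastal_max_y = 20,
                      offshore_min_y = 20, seed = 2)
  lay0 <- gen_layout(tc0)
  expect_false(any(lay0$y_km[lay0$survey == "CTS"] > 20))
  # fixed stations repeat the same positions every year
  tcf <- truth_config(years = 2018:2020, hauls_per_year = c(IBTS = 12L),
                      fixed_stations = TRUE, seed = 3)
  layf <- gen_layout(tcf)
  expect_equal(length(unique(layf$x_km)), 12)
})

test_that("haul positions are uniform within the footprint", {
  tc <- truth_config(years = 2020, hauls_per_year = c(IBTS = 6000L), seed = 44)
  lay <- gen_layout(tc)
  bx <- tabulate(findInterval(lay$x_km, seq(0, 200, by = 20),
                              rightmost.closed = TRUE), 10)
  by <- tabulate(findInterval(lay$y_km, seq(15, 100, length.out = 11),
                              rightmost.closed = TRUE), 10)
  expect_gt(stats::chisq.test(bx)$p.value, 0.01)
  expect_gt(stats::chisq.test(by)$p.value, 0.01)
})

test_that("observations follow the delta model closed forms and reproduce", {
  # all effects zero, no fields: p = 1 - exp(-1) everywhere
  tc <- truth_config(years = 2019:2020, hauls_per_year = c(IBTS = 400L),
                     year_effect_binomial = c(0, 0),
                     year_effect_gamma = c(0, 0),
                     shore_gradient = c(0, 0),
                     sigma_spatial = c(0, 0), sigma_st = c(0, 0),
                     phi = 200, seed = 6)
  h <- gen_observations(gen_layout(tc), tc)
  p0 <- 1 - exp(-1)
  se <- sqrt(p0 * (1 - p0) / nrow(h))
  expect_lt(abs(mean(h$density_per_km2 > 0) - p0), 3 * se)
  # phi large: positive part concentrates at r = 1/p
  expect_equal(mean(h$density_per_km2[h$density_per_km2 > 0]), 1 / p0,
               tolerance = 0.05)

  # bit-identical regeneration from the stored configuration
  h2 <- gen_hauls(tc)
  h3 <- gen_hauls(attr(h2, "truth")$config)
  expect_identical(h2$density_per_km2, h3$density_per_km2)
})

test_that("a shore gradient makes coastal catches exceed offshore catches", {
  tc <- truth_config(years = 2018:2020, shore_gradient = c(-0.05, -0.03),
                     seed = 4)
  h <- gen_hauls(tc)
  m <- tapply(h$density_per_km2, h$survey, mean)
  expect_gt(m[["CTS"]], m[["IBTS"]])
})

test_that("video campaigns draw Poisson counts with the stated mean", {
  tc <- truth_config(seed = 8)
  z <- gen_uwtv_campaign(tc, 87, density_per_km2 = 0)
  expect_true(all(z$count == 0))

  # all-zero probability at 100 items/km2 matches exp(-n * mu)
  zero_runs <- vapply(1:400, function(s) {
    tcs <- truth_config(seed = 8 + s)
    all(gen_uwtv_campaign(tcs, 87, density_per_km2 = 100)$count == 0)
  }, logical(1))
  p_closed <- exp(-87 * 100 * 148e-6)
  se <- sqrt(p_closed * (1 - p_closed) / 400)
  expect_lt(abs(mean(zero_runs) - p_closed), 3 * se)

  # pooled estimate converges on the truth
  big <- gen_uwtv_campaign(truth_config(seed = 9), 20000,
                           density_per_km2 = 5000)
  pooled <- sum(big$count) / (20000 * 148e-6)
  se_pooled <- sqrt(sum(big$count)) / (20000 * 148e-6)
  expect_lt(abs(pooled - 5000), 3 * se_pooled)
})
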