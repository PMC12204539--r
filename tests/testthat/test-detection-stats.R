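test_that("zero-detection probability follows the avoidance closed form", {
  expect_equal(prob_none_detected(0, 100), 1)
  expect_equal(prob_none_detected(10, 50), (1 - 50 * 148 / 1e6)^10,
               tolerance = 1e-12)
  # 500 transects at 50 items/km2: detection probability exceeds 97%
  expect_equal(prob_none_detected(50, 500), (1 - 0.074)^50, tolerance = 1e-12)
  expect_gte(1 - prob_none_detected(50, 500), 0.97)
  expect_error(prob_none_detected(10, 10000), "cover more than")
})

test_that("rule of three reproduces the printed bounds and the exact limit", {
  r95 <- rule_of_three(87)
  expect_equal(r95$lower, 0)
  expect_equal(r95$upper, 3 / 87, tolerance = 1e-12)
  expect_equal(round(r95$upper, 3), 0.034)
  r99 <- rule_of_three(87, 0.99)
  expect_equal(r99$upper, 4.61 / 87, tolerance = 1e-12)
  expect_equal(round(r99$upper, 3), 0.053)
  expect_warning(out <- rule_of_three(30), "more than 30 trials")
  expect_equal(out$upper, 0.1)
  expect_error(rule_of_three(87, 0.9), "level")

  # 3/n tracks the exact zero-success Clopper-Pearson bound 1 - alpha^(1/n);
  # the leading error term is ~log(20)^2 / (2n), so ~3% at n = 50 and
  # under 2% from n = 100 up
  for (n in c(100, 500, 1000)) {
    exact <- 1 - 0.05^(1 / n)
    expect_lt(abs(3 / n - exact) / exact, 0.02)
  }
  expect_lt(abs(3 / 50 - (1 - 0.05^(1 / 50))) / (1 - 0.05^(1 / 50)), 0.035)
})

test_that("Agresti-Coull interval matches its formula and stays in [0, 1]", {
  ac <- agresti_coull_ci(0, 87)
  expect_equal(ac$lower, 0) # clamped
  expect_equal(ac$upper, 0.05072773, tolerance = 1e-6) # frozen from formula
  expect_lte(agresti_coull_ci(87, 87)$upper, 1)
  expect_gte(agresti_coull_ci(87, 87)$lower, 0.9)
  expect_error(agresti_coull_ci(5, 4), "n_trials")

  # zero-success upper bound comparable to 3/n across realistic sample sizes
  for (n in c(50, 100, 200, 500, 1000)) {
    ratio <- agresti_coull_ci(0, n)$upper / rule_of_three(n)$upper
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.6)
  }
})

test_that("expected positives and the implied density bound are consistent", {
  up <- rule_of_three(87)$upper
  expect_equal(expected_positive_transects(up, 87), 3, tolerance = 1e-12)
  expect_equal(expected_positive_transects(0, 87), 0)
  expect_equal(expected_positive_transects(1, 87), 87)

  expect_equal(upper_density_bound(87), 3 / 87 * 1e6 / 148, tolerance = 1e-12)
  expect_equal(round(upper_density_bound(87)), 233)
  expect_equal(upper_density_bound(100), 202.7027, tolerance = 1e-4)
  # vanishing bound with unbounded effort
  expect_lt(upper_density_bound(1e8), 0.001)
  # bookkeeping identity: bound x n x area(km2) = upper fraction x n
  for (n in c(87, 200, 777)) {
    expect_equal(upper_density_bound(n) * n * 148e-6,
                 rule_of_three(n)$upper * n, tolerance = 1e-12)
  }
})

test_that("detection report bundles bounds on both scales", {
  rep87 <- detection_report(87)
  expect_setequal(rep87$method, c("rule_of_three", "agresti_coull"))
  expect_true(all(rep87$lower <= rep87$upper))
  expect_equal(rep87$upper_density_per_km2[rep87$method == "rule_of_three"],
               233, tolerance = 0.01)
})
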