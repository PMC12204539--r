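#' Probability that no litter is detected by n transects
#'
#' Closed-form companion to the grid experiment: with `D` items placed
#' uniformly on a grid of area `A` and `n` disjoint transects of area `a`
#' each, the probability that every item avoids every transect is
#' `(1 - n a / A)^D`, with `D = round(density * A * 1e-6)`. Transects are
#' treated as non-overlapping, a very good approximation at the default
#' scales (coverage fraction at most a few percent).
#'
#' @param density_per_km2 True litter density (items per km^2).
#' @param n_transects Number of transects.
#' @param transect_area_m2 Area of one transect (default 148 m^2).
#' @param grid_area_m2 Total grid area (default 1e6 m^2 = 1 km^2).
#' @return Probability in `[0, 1]` that zero items are captured.
#' @examples
#' prob_none_detected(10, 50)   # ~0.928
#' prob_none_detected(100, 100) # ~0.225
#' @export
prob_none_detected <- function(density_per_km2, n_transects,
                               transect_area_m2 = 148, grid_area_m2 = 1e6) {
  coverage <- n_transects * transect_area_m2 / grid_area_m2
  if (any(coverage > 1)) {
    stop("transects cover more than the whole grid (coverage ",
         max(coverage), ")", call. = FALSE)
  }
  n_items <- round(density_per_km2 * grid_area_m2 * 1e-6)
  (1 - coverage)^n_items
}

new_detection_ci <- function(n_trials, n_successes, level, lower, upper, method) {
  tibble::tibble(method = method, n_trials = as.integer(n_trials),
                 n_successes = as.integer(n_successes), level = level,
                 lower = lower, upper = upper)
}

#' Rule-of-three interval for a probability after all-failure trials
#'
#' After `n` binomial trials with zero successes, the upper confidence bound
#' for the success probability is approximately `3/n` at the 95% level and
#' `4.61/n` at the 99% level (the constants being -log(alpha), with 4.61 used
#' as conventionally printed); the lower bound is 0. Intended for `n` > 30.
#'
#' @param n_trials Number of trials (transects).
#' @param level Confidence level, `0.95` or `0.99`.
#' @return A one-row tibble: `method`, `n_trials`, `n_successes`, `level`,
#'   `lower`, `upper`.
#' @examples
#' rule_of_three(87)        # upper ~0.034
#' rule_of_three(87, 0.99)  # upper ~0.053
#' @export
rule_of_three <- function(n_trials, level = 0.95) {
  stopifnot(n_trials >= 1)
  if (n_trials <= 30) {
    warning("rule of three is intended for more than 30 trials (n = ",
            n_trials, ")", call. = FALSE)
  }
  const <- switch(as.character(level), "0.95" = 3, "0.99" = 4.61,
                  stop("level must be 0.95 or 0.99", call. = FALSE))
  new_detection_ci(n_trials, 0L, level, 0, const / n_trials, "rule_of_three")
}

#' Agresti-Coull binomial confidence interval
#'
#' Adjusted-Wald interval: with `z` the two-sided normal quantile,
#' `n_tilde = n + z^2` and `p_tilde = (k + z^2/2) / n_tilde`, the bounds are
#' `p_tilde +/- z * sqrt(p_tilde (1 - p_tilde) / n_tilde)`, clamped to
#' `[0, 1]`. Useful for exploring how the interval behaves when a few
#' transects do contain litter.
#'
#' @param n_successes Number of successes `k`, `0 <= k <= n`.
#' @param n_trials Number of trials `n`.
#' @param level Confidence level (any value in (0, 1)).
#' @return A one-row tibble as in [rule_of_three()].
#' @export
agresti_coull_ci <- function(n_successes, n_trials, level = 0.95) {
  stopifnot(n_trials >= 1)
  if (n_successes < 0 || n_successes > n_trials) {
    stop("n_successes must lie in [0, n_trials]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  n_tilde <- n_trials + z^2
  p_tilde <- (n_successes + z^2 / 2) / n_tilde
  half <- z * sqrt(p_tilde * (1 - p_tilde) / n_tilde)
  new_detection_ci(n_trials, n_successes, level,
                   max(0, p_tilde - half), min(1, p_tilde + half),
                   "agresti_coull")
}

#' Expected number of litter-positive transects at an upper bound
#'
#' Multiplies an upper confidence bound on the per-transect presence
#' probability by the number of transects; returned unrounded.
#'
#' @param upper_probability Upper bound on per-transect presence probability.
#' @param n_trials Number of transects.
#' @return Expected count (real-valued).
#' @export
expected_positive_transects <- function(upper_probability, n_trials) {
  stopifnot(upper_probability >= 0, upper_probability <= 1)
  upper_probability * n_trials
}

#' Upper bound on mean litter density implied by all-zero transects
#'
#' If the rule-of-three upper-bound fraction of `n` transects each held
#' exactly one item, the mean density over the survey would be
#' `upper * 1e6 / transect_area_m2` items per km^2: the detection-probability
#' bound translated to the density scale (one item in one 148 m^2 transect
#' corresponds to about 6757 items per km^2).
#'
#' @inheritParams rule_of_three
#' @param transect_area_m2 Swept area of one transect.
#' @return Density bound in items per km^2.
#' @examples
#' upper_density_bound(87) # ~233 items/km2
#' @export
upper_density_bound <- function(n_trials, level = 0.95, transect_area_m2 = 148) {
  stopifnot(transect_area_m2 > 0)
  ci <- rule_of_three(n_trials, level)
  ci$upper * 1e6 / transect_area_m2
}

#' Detection-bound summary report for an all-zero survey
#'
#' Convenience wrapper producing, for a survey of `n` transects with zero
#' (or `k`) litter detections, the rule-of-three and Agresti-Coull bounds,
#' the implied upper density bound, and the expected number of positive
#' transects at the upper bound.
#'
#' @inheritParams agresti_coull_ci
#' @param transect_area_m2 Swept area of one transect.
#' @return A tibble with one row per method.
#' @export
detection_report <- function(n_trials, n_successes = 0L, level = 0.95,
                             transect_area_m2 = 148) {
  rows <- dplyr::bind_rows(
    if (n_successes == 0) rule_of_three(n_trials, level),
    agresti_coull_ci(n_successes, n_trials, level)
  )
  dplyr::mutate(
    rows,
    expected_positive = expected_positive_transects(.data$upper, n_trials),
    upper_density_per_km2 = .data$upper * 1e6 / transect_area_m2
  )
}
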