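#' Plot detection-experiment results
#'
#' One panel per litter-density scenario: jittered replicate density
#' estimates against sample size, the across-replicate mean, the true
#' density, and the proportion of all-zero replicates printed above each
#' sample size.
#'
#' @param object A `scenario_result` from [run_experiment()] (with replicate
#'   densities kept).
#' @param n_points Replicate points drawn per scenario cell (subsampled to
#'   avoid overplotting).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_result <- function(object, n_points = 30L, ...) {
  stopifnot("replicate_densities" %in% names(object))
  pts <- tidyr::unnest(
    dplyr::mutate(object, replicate_densities = purrr::map(
      .data$replicate_densities,
      function(v) sample(v, min(n_points, length(v)))
    )),
    "replicate_densities"
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = factor(.data$n_transects))) +
    ggplot2::geom_jitter(ggplot2::aes(y = .data$replicate_densities),
                         width = 0.25, alpha = 0.4, colour = "steelblue",
                         size = 0.8) +
    ggplot2::geom_point(data = object,
                        ggplot2::aes(y = .data$mean_density),
                        colour = "deeppink", size = 2.5, shape = 21,
                        fill = NA, stroke = 1.1) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$density_per_km2),
                        colour = "deeppink") +
    ggplot2::geom_text(data = object,
                       ggplot2::aes(y = Inf,
                                    label = sprintf("%.2f", .data$prop_zero_replicates)),
                       vjust = 1.4, size = 3) +
    ggplot2::facet_wrap(~density_per_km2, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Number of transects",
                  y = "Estimated density (items per km²)",
                  title = "Transect-sampling detection experiment",
                  subtitle = "Top labels: proportion of replicates with zero items") +
    ggplot2::theme_minimal()
}

#' Plot zero-detection upper bounds against sample size
#'
#' Rule-of-three upper confidence bounds for the per-transect presence
#' probability, and the implied upper bound on mean litter density, as
#' functions of the number of all-zero transects.
#'
#' @param n_range Range of transect counts.
#' @param levels Confidence levels (0.95 and/or 0.99).
#' @param transect_area_m2 Swept area per transect.
#' @return A ggplot with two panels (probability and density scales).
#' @export
plot_detection_bounds <- function(n_range = c(31, 500),
                                  levels = c(0.95, 0.99),
                                  transect_area_m2 = 148) {
  n <- seq(n_range[1], n_range[2])
  df <- purrr::map_dfr(levels, function(lv) {
    up <- dplyr::bind_rows(purrr::map(n, rule_of_three, level = lv))$upper
    tibble::tibble(n = n, level = factor(lv), upper_probability = up,
                   upper_density = up * 1e6 / transect_area_m2)
  })
  long <- tidyr::pivot_longer(df, c("upper_probability", "upper_density"),
                              names_to = "scale", values_to = "bound")
  long$scale <- factor(long$scale,
                       levels = c("upper_probability", "upper_density"),
                       labels = c("P(litter present per transect)",
                                  "Mean density (items per km²)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$n, .data$bound,
                                     colour = .data$level)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~scale, scales = "free_y") +
    ggplot2::labs(x = "Number of transects (all without litter)",
                  y = "Upper confidence bound", colour = "Level") +
    ggplot2::theme_minimal()
}

#' Plot annual litter-density indices with the weighted trend
#'
#' @param object A `litter_index` from [annual_index()].
#' @param trend Optional `litter_trend` from [weighted_trend()]; its fitted
#'   line is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.litter_index <- function(object, trend = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$year, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = "Year", y = "Litter density (items per km²)",
                  title = "Standardized annual litter-density index") +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    ab <- stats::coef(trend$model)
    p <- p + ggplot2::geom_abline(intercept = ab[1], slope = ab[2],
                                  colour = "purple")
  }
  p
}

#' QQ plot of simulated quantile residuals
#'
#' Uniform QQ plot of the randomized quantile residuals from
#' [quantile_residuals()]; points on the diagonal indicate a model
#' consistent with the data.
#'
#' @inheritParams quantile_residuals
#' @return A ggplot.
#' @export
plot_residuals <- function(fit, n_sims = 250L, seed = NULL) {
  qr <- quantile_residuals(fit, n_sims, seed)
  n <- nrow(qr)
  df <- tibble::tibble(theoretical = stats::ppoints(n),
                       observed = sort(qr$residual))
  ggplot2::ggplot(df, ggplot2::aes(.data$theoretical, .data$observed)) +
    ggplot2::geom_abline(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Expected quantile (uniform)",
                  y = "Observed residual quantile",
                  title = "Simulated quantile residuals") +
    ggplot2::theme_minimal()
}
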