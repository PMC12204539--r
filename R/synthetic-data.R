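#' Ground-truth configuration for synthetic survey data
#'
#' Describes a two-survey sampling system on a planar ~200 x 100 km shelf
#' domain (x alongshore, y = distance offshore): a coastal survey ("CTS")
#' trawling a near-shore strip and an offshore survey ("IBTS") working a box
#' that partially overlaps the strip. Observations follow the Poisson-link
#' delta model generatively: for each component,
#' `eta = year effect + survey effect + shore gradient + omega + delta_t`,
#' presence ~ Bernoulli(p) and positive density ~ Gamma(phi, mean r).
#'
#' Defaults mirror the monitoring setting the model targets: years
#' 2012-2024, ~40 offshore and ~30 coastal hauls per year, zero true survey
#' effect (so between-survey differences in raw means arise purely from the
#' shore-to-offshore density gradient and sampling footprints), high AR1
#' correlation in the binomial component, moderate in the Gamma component,
#' and year effects tracing a slow decline with a mean index of roughly 34
#' items per km^2.
#'
#' @param years Modelled years.
#' @param hauls_per_year Named vector: hauls per survey-year.
#' @param domain Named vector `x_min, x_max, y_min, y_max` (km).
#' @param coastal_max_y Offshore edge of the coastal strip (km).
#' @param offshore_min_y Inshore edge of the offshore box (km); below
#'   `coastal_max_y` the two footprints overlap.
#' @param year_effect_binomial,year_effect_gamma True year effects per
#'   component (length of `years`); defaults described above.
#' @param survey_effect Length-2 (binomial, Gamma) additive effect of the
#'   coastal survey relative to the offshore survey; default `c(0, 0)`.
#' @param shore_gradient Length-2 coefficient (per km offshore) on
#'   `y_km - shore_center`; negative values put more litter near shore.
#' @param shore_center Centring constant for the gradient term (km).
#' @param sigma_spatial,sigma_st Length-2 marginal SDs of the time-constant
#'   spatial field and of the AR1 spatiotemporal field, per component.
#' @param range_km Matern correlation range (km).
#' @param anisotropy_ratio,anisotropy_angle Geometric anisotropy of the
#'   fields (default: correlation extends twice as far alongshore).
#' @param rho Length-2 AR1 coefficients (binomial, Gamma).
#' @param phi Gamma shape.
#' @param fixed_stations If `TRUE`, each survey samples the same station
#'   locations every year (fixed-station design, as coastal trawl surveys
#'   typically do); default `FALSE` redraws haul positions each year.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(years = 2012:2024,
                         hauls_per_year = c(IBTS = 40L, CTS = 30L),
                         domain = c(x_min = 0, x_max = 200,
                                    y_min = 0, y_max = 100),
                         coastal_max_y = 25,
                         offshore_min_y = 15,
                         year_effect_binomial = NULL,
                         year_effect_gamma = NULL,
                         survey_effect = c(0, 0),
                         shore_gradient = c(-0.03, -0.015),
                         shore_center = 40,
                         sigma_spatial = c(0.4, 0.3),
                         sigma_st = c(0.6, 0.5),
                         range_km = 30,
                         anisotropy_ratio = 2,
                         anisotropy_angle = 0,
                         rho = c(0.95, 0.75),
                         phi = 1,
                         fixed_stations = FALSE,
                         seed = 1L) {
  T_ <- length(years)
  if (is.null(year_effect_binomial)) {
    year_effect_binomial <- rep(-0.4, T_)
  }
  if (is.null(year_effect_gamma)) {
    # log combined index declining from ~60 to ~18 items/km2 with wiggle,
    # mean close to 34
    log_index <- seq(log(60), log(18), length.out = T_) +
      0.25 * sin(seq_len(T_))
    year_effect_gamma <- log_index - year_effect_binomial
  }
  stopifnot(length(year_effect_binomial) == T_,
            length(year_effect_gamma) == T_,
            all(c(sigma_spatial, sigma_st) >= 0), range_km > 0,
            anisotropy_ratio >= 1, all(abs(rho) < 1), phi > 0,
            offshore_min_y < domain[["y_max"]],
            coastal_max_y > domain[["y_min"]])
  if (offshore_min_y >= coastal_max_y) {
    message("footprints do not overlap (offshore_min_y >= coastal_max_y)")
  }
  structure(
    list(years = years, hauls_per_year = hauls_per_year, domain = domain,
         coastal_max_y = coastal_max_y, offshore_min_y = offshore_min_y,
         year_effect_binomial = year_effect_binomial,
         year_effect_gamma = year_effect_gamma,
         survey_effect = survey_effect, shore_gradient = shore_gradient,
         shore_center = shore_center,
         sigma_spatial = sigma_spatial, sigma_st = sigma_st,
         range_km = range_km, anisotropy_ratio = anisotropy_ratio,
         anisotropy_angle = anisotropy_angle, rho = rho, phi = phi,
         fixed_stations = isTRUE(fixed_stations),
         seed = as.integer(seed)),
    class = "truth_config"
  )
}

#' True annual index implied by a truth configuration
#'
#' @param truth A [truth_config()].
#' @return Tibble `year`, `true_index` (= `exp(year_effect_binomial +
#'   year_effect_gamma)`, the fixed-effects-only mean density at the
#'   offshore reference with the gradient at its centring point).
#' @export
true_annual_index <- function(truth) {
  tibble::tibble(year = truth$years,
                 true_index = exp(truth$year_effect_binomial +
                                    truth$year_effect_gamma))
}

#' Generate the haul sampling layout
#'
#' Uniform haul positions within each survey's footprint for every year:
#' the offshore survey in the box `y_km` in `[offshore_min_y, y_max]`, the
#' coastal survey in the strip `y_km` in `[y_min, coastal_max_y]` (which
#' includes the overlap zone when the footprints overlap).
#'
#' @param truth A [truth_config()].
#' @return Tibble `survey`, `year`, `x_km`, `y_km`.
#' @export
gen_layout <- function(truth) {
  stopifnot(inherits(truth, "truth_config"))
  d <- truth$domain
  if (truth$offshore_min_y >= d[["y_max"]] ||
      truth$coastal_max_y <= d[["y_min"]]) {
    stop("empty survey footprint", call. = FALSE)
  }
  set.seed(truth$seed)
  strata <- list(
    IBTS = c(truth$offshore_min_y, d[["y_max"]]),
    CTS = c(d[["y_min"]], truth$coastal_max_y)
  )
  strata <- strata[intersect(names(strata), names(truth$hauls_per_year))]
  if (!length(strata)) stop("hauls_per_year names no known survey", call. = FALSE)
  stations <- purrr::imap(strata, function(yrange, sv) {
    n <- truth$hauls_per_year[[sv]]
    tibble::tibble(
      survey = sv,
      x_km = stats::runif(n, d[["x_min"]], d[["x_max"]]),
      y_km = stats::runif(n, yrange[1], yrange[2])
    )
  })
  rows <- purrr::map(truth$years, function(yr) {
    per_survey <- if (truth$fixed_stations) {
      stations
    } else {
      purrr::imap(strata, function(yrange, sv) {
        n <- truth$hauls_per_year[[sv]]
        tibble::tibble(
          survey = sv,
          x_km = stats::runif(n, d[["x_min"]], d[["x_max"]]),
          y_km = stats::runif(n, yrange[1], yrange[2])
        )
      })
    }
    dplyr::mutate(dplyr::bind_rows(per_survey), year = yr, .after = "survey")
  })
  dplyr::bind_rows(rows)
}

#' Generate haul observations from the truth
#'
#' Simulates the latent spatial and AR1 spatiotemporal fields at all haul
#' locations and draws each haul's observed density through the Poisson-link
#' delta model. The complete generative state (configuration, per-haul linear
#' predictors, field values, true index) is attached as attribute `"truth"`
#' so downstream recovery tests can compare against it.
#'
#' @param layout Tibble from [gen_layout()].
#' @param truth The [truth_config()] used for the layout.
#' @return Haul tibble `survey`, `year`, `x_km`, `y_km`, `density_per_km2`
#'   with attribute `"truth"`.
#' @export
gen_observations <- function(layout, truth) {
  stopifnot(inherits(truth, "truth_config"))
  set.seed(truth$seed + 1L)
  n <- nrow(layout)
  T_ <- length(truth$years)
  yi <- match(layout$year, truth$years)
  locs <- cbind(layout$x_km, layout$y_km)

  fld <- list()
  for (c in 1:2) {
    om <- if (truth$sigma_spatial[c] > 0) {
      simulate_fields(locs, truth$sigma_spatial[c], truth$range_km,
                      truth$anisotropy_angle, truth$anisotropy_ratio,
                      n_years = 1L)$omega
    } else numeric(n)
    de <- if (truth$sigma_st[c] > 0) {
      simulate_fields(locs, truth$sigma_st[c], truth$range_km,
                      truth$anisotropy_angle, truth$anisotropy_ratio,
                      n_years = T_, rho = truth$rho[c])$delta
    } else matrix(0, n, T_)
    fld[[c]] <- list(omega = om, delta = de)
  }

  coastal <- layout$survey == "CTS"
  grad <- layout$y_km - truth$shore_center
  eta1 <- truth$year_effect_binomial[yi] +
    truth$survey_effect[1] * coastal + truth$shore_gradient[1] * grad +
    fld[[1]]$omega + fld[[1]]$delta[cbind(seq_len(n), yi)]
  eta2 <- truth$year_effect_gamma[yi] +
    truth$survey_effect[2] * coastal + truth$shore_gradient[2] * grad +
    fld[[2]]$omega + fld[[2]]$delta[cbind(seq_len(n), yi)]

  link <- poisson_link(eta1, eta2)
  pres <- stats::rbinom(n, 1, link$p) == 1
  y <- numeric(n)
  y[pres] <- stats::rgamma(sum(pres), shape = truth$phi,
                           scale = link$r[pres] / truth$phi)
  out <- dplyr::mutate(tibble::as_tibble(layout), density_per_km2 = y)
  attr(out, "truth") <- list(
    config = truth, eta1 = eta1, eta2 = eta2, p = link$p, r = link$r,
    fields = fld, true_index = true_annual_index(truth)
  )
  out
}

#' Generate a full synthetic haul dataset
#'
#' Convenience wrapper: [gen_layout()] then [gen_observations()].
#'
#' @param truth A [truth_config()].
#' @return Haul tibble with attribute `"truth"`.
#' @export
gen_hauls <- function(truth = truth_config()) {
  gen_observations(gen_layout(truth), truth)
}

#' Generate an underwater-video transect campaign
#'
#' Places `n_transects` video transects of `transect_area_m2` uniformly in
#' the offshore footprint and draws per-transect litter counts as Poisson
#' with mean `local density x area`: the thinned-point-process limit of the
#' grid experiment, suitable for studying the probability that the whole
#' campaign comes back empty under low densities.
#'
#' @param truth A [truth_config()].
#' @param n_transects Number of transects.
#' @param year Year of the campaign (defaults to the last configured year).
#' @param density_per_km2 Optional constant true density overriding the
#'   truth's (fixed-effect + gradient) density surface.
#' @param transect_area_m2 Swept area per transect.
#' @return Tibble `x_km`, `y_km`, `true_density_per_km2`, `count`,
#'   `est_density_per_km2`.
#' @export
gen_uwtv_campaign <- function(truth, n_transects = 87L,
                              year = max(truth$years),
                              density_per_km2 = NULL,
                              transect_area_m2 = 148) {
  stopifnot(inherits(truth, "truth_config"), n_transects >= 1)
  set.seed(truth$seed + 2L)
  d <- truth$domain
  x <- stats::runif(n_transects, d[["x_min"]], d[["x_max"]])
  y <- stats::runif(n_transects, truth$offshore_min_y, d[["y_max"]])
  dens <- if (!is.null(density_per_km2)) {
    rep(density_per_km2, n_transects)
  } else {
    yi <- match(year, truth$years)
    if (is.na(yi)) stop("year outside the configured span", call. = FALSE)
    grad <- y - truth$shore_center
    exp(truth$year_effect_binomial[yi] + truth$shore_gradient[1] * grad +
          truth$year_effect_gamma[yi] + truth$shore_gradient[2] * grad)
  }
  count <- stats::rpois(n_transects, dens * transect_area_m2 * 1e-6)
  tibble::tibble(x_km = x, y_km = y, true_density_per_km2 = dens,
                 count = count,
                 est_density_per_km2 = count / (transect_area_m2 * 1e-6))
}
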