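#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a delta-model fit
#'
#' One row per estimated parameter, broom-style. Fixed effects are reported
#' on the linear-predictor (log) scale; field hyperparameters are
#' back-transformed to their natural scales (`sigma`, `range` in km,
#' anisotropy `ratio`, AR1 `rho`, Gamma shape `phi`) with Wald intervals
#' formed on the estimation scale and then transformed. Anisotropy is
#' reported in canonical form (ratio >= 1): an estimated ratio below 1 is
#' the identical covariance as its reciprocal with the angle rotated 90
#' degrees, and is relabelled accordingly.
#'
#' @param x A `litter_delta_fit`.
#' @param conf_level Confidence level for `conf.low`/`conf.high`.
#' @param ... Unused.
#' @return Tibble with `component`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.litter_delta_fit <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$sdr, "fixed")
  est <- s[, "Estimate"]; se <- s[, "Std. Error"]
  nm <- rownames(s)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- est - z * se; hi <- est + z * se

  term_for <- function(i, comp) {
    cols <- c(paste0("year_", x$years),
              if (length(x$survey_cols)) paste0("survey_", names(x$survey_cols)))
    cols[i]
  }
  rows <- list()
  for (comp in 1:2) {
    pn <- paste0("beta", comp)
    i <- which(nm == pn)
    if (length(i)) {
      rows[[pn]] <- tibble::tibble(
        component = c("binomial", "gamma")[comp],
        term = term_for(seq_along(i), comp),
        estimate = est[i], std.error = se[i],
        conf.low = lo[i], conf.high = hi[i]
      )
    }
  }
  hyper <- list(
    log_sigma = list(name = "sigma", trans = exp),
    log_range = list(name = "range", trans = exp),
    angle = list(name = "anisotropy_angle", trans = identity),
    log_ratio = list(name = "anisotropy_ratio", trans = exp),
    trans_rho = list(name = "rho", trans = function(v) 2 / (1 + exp(-v)) - 1)
  )
  comp_names <- c("binomial", "gamma")
  for (h in names(hyper)) {
    i <- which(nm == h)
    if (!length(i)) next
    # mapped-off components drop out of the parameter vector; recover which
    # component each remaining entry belongs to from the field structure
    active <- switch(h,
      trans_rho = which(x$field_types == 2),
      angle = , log_ratio = which(x$field_types > 0 & x$spec$anisotropy),
      which(x$field_types > 0))
    tr <- hyper[[h]]$trans
    rows[[h]] <- tibble::tibble(
      component = comp_names[active],
      term = hyper[[h]]$name,
      estimate = tr(est[i]), std.error = se[i],
      conf.low = tr(lo[i]), conf.high = tr(hi[i])
    )
  }
  i <- which(nm == "log_phi")
  rows$log_phi <- tibble::tibble(
    component = "gamma", term = "phi", estimate = exp(est[i]),
    std.error = se[i], conf.low = exp(lo[i]), conf.high = exp(hi[i])
  )
  out <- dplyr::bind_rows(rows)

  # canonicalize the anisotropy labelling: a ratio below 1 is the same
  # covariance as its reciprocal with the angle rotated by 90 degrees
  if (!is.null(rows$log_ratio)) {
    for (comp in rows$log_ratio$component) {
      ir <- which(out$term == "anisotropy_ratio" & out$component == comp)
      ia <- which(out$term == "anisotropy_angle" & out$component == comp)
      if (length(ir) == 1 && out$estimate[ir] < 1) {
        out[ir, c("estimate", "conf.low", "conf.high")] <-
          as.list(1 / unlist(out[ir, c("estimate", "conf.high", "conf.low")]))
        a_raw <- out$estimate[ia] + pi / 2
        a_new <- ((a_raw + pi / 2) %% pi) - pi / 2 # wrap to (-pi/2, pi/2]
        shift <- a_new - out$estimate[ia]          # pi/2 plus any wrap
        out[ia, c("estimate", "conf.low", "conf.high")] <-
          as.list(c(a_new, out$conf.low[ia] + shift, out$conf.high[ia] + shift))
      }
    }
  }
  out
}

#' One-row summary of a delta-model fit
#'
#' @param x A `litter_delta_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `AIC`, `df`, `nobs`, `pd_hessian`,
#'   `max_gradient`, `converged`.
#' @export
glance.litter_delta_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, AIC = x$aic, df = x$npar, nobs = nrow(x$data),
    pd_hessian = x$diagnostics$pd_hessian,
    max_gradient = x$diagnostics$max_gradient,
    converged = x$diagnostics$pd_hessian && x$diagnostics$gradient_ok
  )
}

#' Tidy a weighted-trend fit
#'
#' @param x A `litter_trend`.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `conf.low`, `conf.high`,
#'   `level`, `weighting`.
#' @export
tidy.litter_trend <- function(x, ...) {
  tibble::tibble(term = "year", estimate = x$slope,
                 conf.low = x$conf_low, conf.high = x$conf_high,
                 level = x$level, weighting = x$weighting)
}
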