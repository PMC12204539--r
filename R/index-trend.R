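#' Standardized annual litter-density index
#'
#' Fixed-effects-only ("conditional, omitting the random effects") annual
#' density estimates at the reference survey level: for each year `y` the
#' index is `exp(beta1_y + beta2_y)`, the Poisson-link unconditional mean.
#' Uncertainty comes from the joint fixed-effect covariance, either by the
#' delta method on the log scale (`method = "wald"`: log-scale SE, interval
#' `exp(log estimate +/- z se)`) or by simulating parameter vectors from the
#' estimated covariance (`method = "sim"`).
#'
#' @param fit A converged `litter_delta_fit`.
#' @param level Confidence level for the interval.
#' @param method `"wald"` (default) or `"sim"`.
#' @param n_sims Parameter draws for `method = "sim"`.
#' @param seed Optional seed for `method = "sim"`.
#' @return A tibble of class `litter_index`: `year`, `estimate` (items per
#'   km^2), `se`, `cv` (= se/estimate), `lo`, `hi`.
#' @export
annual_index <- function(fit, level = 0.95, method = c("wald", "sim"),
                         n_sims = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "litter_delta_fit"))
  method <- match.arg(method)
  V <- fit$sdr$cov.fixed
  if (is.null(V) || any(!is.finite(V))) {
    stop("fit has no usable parameter covariance; check convergence ",
         "diagnostics", call. = FALSE)
  }
  par_names <- names(fit$opt$par)
  i1 <- which(par_names == "beta1")[fit$year_cols]
  i2 <- which(par_names == "beta2")[fit$year_cols]
  est_log <- unname(fit$opt$par[i1] + fit$opt$par[i2])
  z <- stats::qnorm(1 - (1 - level) / 2)

  if (method == "wald") {
    se_log <- sqrt(diag(V)[i1] + diag(V)[i2] + 2 * V[cbind(i1, i2)])
    estimate <- exp(est_log)
    out <- tibble::tibble(
      year = fit$years, estimate = estimate,
      se = estimate * se_log, cv = se_log,
      lo = exp(est_log - z * se_log), hi = exp(est_log + z * se_log)
    )
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- c(i1, i2)
    draws <- rmvn_chol(n_sims, V[idx, idx])        # centred draws
    Ty <- length(fit$years)
    log_draws <- sweep(draws[, seq_len(Ty)] + draws[, Ty + seq_len(Ty)],
                       2, est_log, "+")
    sims <- exp(log_draws)
    estimate <- exp(est_log)
    out <- tibble::tibble(
      year = fit$years, estimate = estimate,
      se = apply(sims, 2, stats::sd),
      cv = apply(sims, 2, stats::sd) / estimate,
      lo = apply(sims, 2, stats::quantile, probs = (1 - level) / 2),
      hi = apply(sims, 2, stats::quantile, probs = 1 - (1 - level) / 2)
    )
  }
  class(out) <- c("litter_index", class(out))
  out
}

#' CV-weighted linear trend in annual indices
#'
#' Weighted least-squares regression of the annual index on year, with
#' weights the inverse CV of each year's estimate (the convention used for
#' the published trend; `weights = "inverse_cv2"` switches to
#' inverse-squared-CV, i.e. inverse relative variance). The slope interval
#' uses the t distribution with `n_years - 2` degrees of freedom.
#'
#' @param indices A `litter_index` tibble from [annual_index()] (any data
#'   frame with `year`, `estimate`, `cv` works).
#' @param level Confidence level.
#' @param weights `"inverse_cv"` (default) or `"inverse_cv2"`.
#' @return A list of class `litter_trend`: `slope` (items per km^2 per
#'   year), `conf_low`, `conf_high`, `level`, `weights` (the weight vector),
#'   and the underlying `lm` fit.
#' @export
weighted_trend <- function(indices, level = 0.95,
                           weights = c("inverse_cv", "inverse_cv2")) {
  weights <- match.arg(weights)
  stopifnot(all(c("year", "estimate", "cv") %in% names(indices)))
  if (nrow(indices) < 3) stop("need at least 3 years", call. = FALSE)
  if (any(indices$cv <= 0)) {
    stop("all CVs must be strictly positive", call. = FALSE)
  }
  w <- if (weights == "inverse_cv") 1 / indices$cv else 1 / indices$cv^2
  m <- stats::lm(estimate ~ year, data = indices, weights = w)
  ci <- stats::confint(m, "year", level = level)
  structure(
    list(slope = unname(stats::coef(m)["year"]),
         conf_low = ci[1], conf_high = ci[2], level = level,
         weighting = weights, weights = w, model = m),
    class = "litter_trend"
  )
}

#' @export
print.litter_trend <- function(x, ...) {
  cat("<litter_trend> weighted linear trend (", x$weighting, " weights)\n",
      sep = "")
  cat(sprintf("  slope: %.4g items/km2/year [%g%% CI: %.4g, %.4g]\n",
              x$slope, 100 * x$level, x$conf_low, x$conf_high))
  invisible(x)
}
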