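#' Specify a Poisson-link delta geostatistical model
#'
#' Defines the random-effect structure and fitting options for the two-part
#' (binomial x Gamma) litter-density model. Each component carries at most
#' one latent Gaussian field: a time-constant spatial field (`"spatial"`), a
#' yearly field with AR1 correlation between consecutive years (`"st_ar1"`),
#' or no field (`"none"`, the GLM limit). The three candidate structures used
#' for model selection are spatial/spatial, st_ar1/st_ar1, and
#' spatial/st_ar1.
#'
#' @param binomial,gamma Field structure per model component: `"spatial"`,
#'   `"st_ar1"` or `"none"`.
#' @param anisotropy Estimate geometric anisotropy (rotation angle and
#'   stretch ratio) of the Matern correlation? When `FALSE` fields are
#'   isotropic. Anisotropy parameters are only meaningful when at least one
#'   component has a field.
#' @param reference_survey Survey level absorbed into the year intercepts;
#'   defaults to the first level in sort order. Annual indices are reported
#'   at this level.
#' @param n_knots Number of field knot locations (k-means centres of the haul
#'   positions; fields are read at the nearest knot).
#' @param field_sd_threshold Flag threshold for the field-hyperparameter
#'   standard-error diagnostic (internal, log/logit scale).
#' @param nlminb_control Control list passed to [stats::nlminb()].
#' @param newton_restarts Number of optimizer restarts from the previous
#'   optimum (cheap insurance against premature convergence).
#' @param knot_seed Seed for the deterministic k-means knot placement.
#' @return A list of class `delta_spec`.
#' @export
delta_spec <- function(binomial = c("spatial", "st_ar1", "none"),
                       gamma = c("st_ar1", "spatial", "none"),
                       anisotropy = FALSE,
                       reference_survey = NULL,
                       n_knots = 25L,
                       field_sd_threshold = 10,
                       nlminb_control = list(iter.max = 2000L, eval.max = 3000L),
                       newton_restarts = 1L,
                       knot_seed = 1L) {
  structure(
    list(binomial = match.arg(binomial), gamma = match.arg(gamma),
         anisotropy = isTRUE(anisotropy),
         reference_survey = reference_survey,
         n_knots = as.integer(n_knots),
         field_sd_threshold = field_sd_threshold,
         nlminb_control = nlminb_control,
         newton_restarts = as.integer(newton_restarts),
         knot_seed = as.integer(knot_seed)),
    class = "delta_spec"
  )
}

field_code <- function(x) c(none = 0L, spatial = 1L, st_ar1 = 2L)[[x]]

# Run code with a temporary RNG state (used for deterministic k-means).
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Validate hauls, build factor levels, design matrix and knot projection.
prepare_delta_data <- function(hauls, spec) {
  hauls <- tibble::as_tibble(hauls)
  needed <- c("survey", "year", "x_km", "y_km", "density_per_km2")
  missing_cols <- setdiff(needed, names(hauls))
  if (length(missing_cols)) {
    stop("hauls is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(hauls$density_per_km2 < 0)) stop("negative densities", call. = FALSE)
  if (!all(is.finite(hauls$x_km)) || !all(is.finite(hauls$y_km))) {
    stop("non-finite coordinates", call. = FALSE)
  }

  # a survey with no positive observations cannot inform the Gamma component
  # (nor, jointly, its catchability contrast): exclude it from fitting
  any_pos <- tapply(hauls$density_per_km2 > 0, hauls$survey, any)
  drop <- names(any_pos)[!any_pos]
  if (length(drop)) {
    message("excluding survey level(s) with no positive observations: ",
            paste(drop, collapse = ", "))
    hauls <- dplyr::filter(hauls, !(.data$survey %in% drop))
  }
  if (nrow(hauls) == 0 || !any(hauls$density_per_km2 > 0)) {
    stop("no positive observations left to fit the Gamma component",
         call. = FALSE)
  }

  years <- sort(unique(hauls$year))
  gap <- setdiff(seq(min(years), max(years)), years)
  if (length(gap)) {
    stop("years without hauls inside the modelled span: ",
         paste(gap, collapse = ", "), "; every modelled year needs >= 1 haul",
         call. = FALSE)
  }
  if (length(years) < 2) stop("need hauls from at least 2 years", call. = FALSE)

  survey_levels <- sort(unique(as.character(hauls$survey)))
  ref <- spec$reference_survey %||% survey_levels[1]
  if (!ref %in% survey_levels) {
    stop("reference survey '", ref, "' not among fitted levels (",
         paste(survey_levels, collapse = ", "), ")", call. = FALSE)
  }
  survey_levels <- c(ref, setdiff(survey_levels, ref))

  yr <- factor(hauls$year, levels = years)
  sv <- factor(as.character(hauls$survey), levels = survey_levels)
  X <- if (length(survey_levels) > 1) {
    stats::model.matrix(~ 0 + yr + sv)
  } else {
    stats::model.matrix(~ 0 + yr)
  }
  year_cols <- seq_along(years)
  survey_cols <- if (length(survey_levels) > 1) {
    stats::setNames(length(years) + seq_len(length(survey_levels) - 1),
                    survey_levels[-1])
  } else {
    integer(0)
  }

  coords <- cbind(hauls$x_km, hauls$y_km)
  uniq <- unique(coords)
  if (nrow(uniq) < 2) stop("need at least 2 distinct locations", call. = FALSE)
  if (nrow(uniq) <= spec$n_knots) {
    knots <- uniq
    knot_i <- match(
      paste(coords[, 1], coords[, 2]), paste(uniq[, 1], uniq[, 2])
    )
  } else {
    km <- with_local_seed(
      spec$knot_seed,
      stats::kmeans(coords, centers = spec$n_knots, nstart = 3L,
                    iter.max = 100L)
    )
    knots <- km$centers
    knot_i <- km$cluster
  }

  list(hauls = hauls, years = years, survey_levels = survey_levels,
       reference_survey = ref, X = X, year_cols = year_cols,
       survey_cols = survey_cols, knots = unname(knots),
       knot_i = as.integer(knot_i),
       year_i = as.integer(match(hauls$year, years)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Starting values: moment-match the overall encounter rate and positive mean.
delta_start <- function(prep, ft) {
  y <- prep$hauls$density_per_km2
  pbar <- min(max(mean(y > 0), 0.02), 0.98)
  b1 <- log(-log(1 - pbar))
  b2 <- log(max(mean(y), 0.1)) - b1
  p <- ncol(prep$X)
  beta1 <- rep(0, p); beta1[prep$year_cols] <- b1
  beta2 <- rep(0, p); beta2[prep$year_cols] <- b2
  K <- nrow(prep$knots); T_ <- length(prep$years)
  d <- stats::dist(prep$knots)
  list(beta1 = beta1, beta2 = beta2,
       log_sigma = rep(log(0.5), 2),
       log_range = rep(log(max(stats::median(d), 1e-2)), 2),
       angle = c(0, 0), log_ratio = c(0, 0), trans_rho = c(0, 0),
       log_phi = 0,
       omega = matrix(0, K, 2),
       delta1 = array(0, c(K, T_)), delta2 = array(0, c(K, T_)))
}

# TMB map list switching off parameters the structure does not use.
delta_map <- function(prep, spec, ft) {
  vec2 <- function(active) factor(ifelse(active, seq_len(2), NA))
  has_field <- ft > 0
  aniso_on <- has_field & spec$anisotropy
  map <- list(
    log_sigma = vec2(has_field), log_range = vec2(has_field),
    angle = vec2(aniso_on), log_ratio = vec2(aniso_on),
    trans_rho = vec2(ft == 2)
  )
  K <- nrow(prep$knots); T_ <- length(prep$years)
  om <- matrix(NA_integer_, K, 2)
  for (c in 1:2) if (ft[c] == 1) om[, c] <- (c - 1) * K + seq_len(K)
  map$omega <- factor(om)
  if (ft[1] != 2) map$delta1 <- factor(rep(NA, K * T_))
  if (ft[2] != 2) map$delta2 <- factor(rep(NA, K * T_))
  map
}

# Assemble TMB data/parameter/map/random lists for a prepared dataset.
build_tmb_inputs <- function(prep, spec, pars = NULL) {
  ft <- c(field_code(spec$binomial), field_code(spec$gamma))
  list(
    ft = ft,
    data = list(
      y = prep$hauls$density_per_km2,
      X = unname(prep$X),
      year_i = prep$year_i - 1L,
      knot_i = prep$knot_i - 1L,
      knot_xy = prep$knots,
      ftype1 = ft[1], ftype2 = ft[2]
    ),
    pars = pars %||% delta_start(prep, ft),
    map = delta_map(prep, spec, ft),
    random = c(
      if (any(ft == 1)) "omega",
      if (ft[1] == 2) "delta1",
      if (ft[2] == 2) "delta2"
    )
  )
}

#' Fit the Poisson-link delta geostatistical GLMM
#'
#' Estimates year and survey fixed effects for both model components together
#' with the Matern field hyperparameters, AR1 coefficients and Gamma shape by
#' maximum marginal likelihood: the latent fields are integrated out with the
#' Laplace approximation (inner Newton optimization over field values), and
#' the outer problem is solved with [stats::nlminb()] using exact
#' automatic-differentiation gradients. Variance parameters are estimated on
#' the log scale and AR1 coefficients on a scaled-logit scale mapping to
#' (-1, 1).
#'
#' Convergence is diagnosed, never assumed: the returned object records
#' whether the Hessian of the fixed and hyperparameters is positive definite,
#' the maximum absolute marginal-likelihood gradient (criterion 1e-3), and a
#' configurable flag for implausibly large field-hyperparameter standard
#' errors. A warning is issued when any check fails.
#'
#' @param hauls Data frame of haul records with columns `survey`, `year`,
#'   `x_km`, `y_km`, `density_per_km2`. Survey levels with no positive
#'   observations are excluded (with a message), mirroring the exclusion of
#'   an all-zero video survey from model fitting.
#' @param spec A [delta_spec()].
#' @param silent Suppress TMB inner-optimization trace.
#' @return An object of class `litter_delta_fit`; see [tidy.litter_delta_fit()]
#'   and [glance.litter_delta_fit()] for tabular summaries, [predict.litter_delta_fit()]
#'   for predictions and [annual_index()] for standardized indices.
#' @export
fit_delta_glmm <- function(hauls, spec = delta_spec(), silent = TRUE) {
  stopifnot(inherits(spec, "delta_spec"))
  prep <- prepare_delta_data(hauls, spec)
  inp <- build_tmb_inputs(prep, spec)
  ft <- inp$ft

  obj <- TMB::MakeADFun(inp$data, inp$pars, map = inp$map,
                        random = inp$random,
                        DLL = "litterindex", silent = silent)
  opt <- stats::nlminb(obj$par, obj$fn, obj$gr,
                       control = spec$nlminb_control)
  for (i in seq_len(spec$newton_restarts)) {
    opt <- stats::nlminb(opt$par, obj$fn, obj$gr,
                         control = spec$nlminb_control)
  }
  sdr <- TMB::sdreport(obj, getReportCovariance = FALSE)
  max_grad <- max(abs(obj$gr(opt$par)))

  fixed <- summary(sdr, "fixed")
  hyper_rows <- rownames(fixed) %in%
    c("log_sigma", "log_range", "angle", "log_ratio", "trans_rho", "log_phi")
  diagnostics <- list(
    pd_hessian = isTRUE(sdr$pdHess),
    max_gradient = max_grad,
    gradient_ok = max_grad < 1e-3,
    field_sd_flag = any(fixed[hyper_rows, "Std. Error"] >
                          spec$field_sd_threshold, na.rm = TRUE),
    nlminb_convergence = opt$convergence,
    nlminb_message = opt$message
  )
  if (!diagnostics$pd_hessian || !diagnostics$gradient_ok) {
    warning("model did not meet convergence criteria (pd_hessian = ",
            diagnostics$pd_hessian, ", max |gradient| = ",
            signif(max_grad, 3), ")", call. = FALSE)
  }

  k <- length(opt$par)
  fit <- structure(
    list(spec = spec, data = prep$hauls, years = prep$years,
         survey_levels = prep$survey_levels,
         reference_survey = prep$reference_survey,
         year_cols = prep$year_cols, survey_cols = prep$survey_cols,
         knots = prep$knots, knot_i = prep$knot_i, year_i = prep$year_i,
         field_types = stats::setNames(ft, c("binomial", "gamma")),
         obj = obj, opt = opt, sdr = sdr,
         parlist = obj$env$parList(par = obj$env$last.par.best),
         logLik = -opt$objective, npar = k,
         aic = 2 * k + 2 * opt$objective,
         diagnostics = diagnostics),
    class = "litter_delta_fit"
  )
  fit
}

#' @export
print.litter_delta_fit <- function(x, ...) {
  cat("<litter_delta_fit> Poisson-link delta GLMM\n")
  cat("  components: binomial [", x$spec$binomial, "], Gamma [",
      x$spec$gamma, "]\n", sep = "")
  cat("  ", nrow(x$data), " hauls, ", length(x$years), " years (",
      min(x$years), "-", max(x$years), "), surveys: ",
      paste(x$survey_levels, collapse = ", "),
      " (reference ", x$reference_survey, ")\n", sep = "")
  cat("  log-likelihood ", format(x$logLik, digits = 6), ", AIC ",
      format(x$aic, digits = 6), " (", x$npar, " parameters)\n", sep = "")
  ok <- x$diagnostics$pd_hessian && x$diagnostics$gradient_ok
  cat("  convergence:", if (ok) "ok" else "NOT OK",
      sprintf("(max |grad| %.2g)\n", x$diagnostics$max_gradient))
  invisible(x)
}

#' Marginal AIC of a delta-model fit
#'
#' `2k - 2 logL` with `k` the number of fixed-effect and hyperparameter
#' entries (random effects excluded, the likelihood being marginal).
#'
#' @param fit A `litter_delta_fit`.
#' @return AIC (scalar).
#' @export
marginal_aic <- function(fit) {
  stopifnot(inherits(fit, "litter_delta_fit"))
  fit$aic
}

#' Compare candidate field structures by marginal AIC
#'
#' @param fits Named list of `litter_delta_fit` objects fitted to the same
#'   hauls.
#' @return A tibble with `model`, `binomial`, `gamma`, `logLik`, `df`, `aic`
#'   and `delta_aic` (AIC minus the smallest AIC), sorted by AIC. The
#'   minimum-AIC model name is in attribute `"best"`.
#' @export
select_model <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "litter_delta_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  same_data <- vapply(fits, function(f) isTRUE(all.equal(f$data, fits[[1]]$data)),
                      logical(1))
  if (!all(same_data)) {
    stop("fits were not produced from identical haul data; AIC comparison ",
         "is only meaningful on the same data", call. = FALSE)
  }
  tab <- tibble::tibble(
    model = names(fits),
    binomial = unname(vapply(fits, function(f) f$spec$binomial, character(1))),
    gamma = unname(vapply(fits, function(f) f$spec$gamma, character(1))),
    logLik = unname(vapply(fits, function(f) f$logLik, numeric(1))),
    df = unname(vapply(fits, function(f) f$npar, numeric(1))),
    aic = unname(vapply(fits, marginal_aic, numeric(1)))
  )
  tab <- dplyr::arrange(dplyr::mutate(tab, delta_aic = .data$aic - min(.data$aic)),
                        .data$aic)
  attr(tab, "best") <- tab$model[1]
  tab
}

# Design matrix for new data in the fitted column layout.
build_design <- function(fit, newdata) {
  n <- nrow(newdata)
  p <- length(fit$year_cols) + length(fit$survey_cols)
  X <- matrix(0, n, p)
  yi <- match(newdata$year, fit$years)
  if (anyNA(yi)) {
    stop("year(s) outside fitted levels: ",
         paste(unique(newdata$year[is.na(yi)]), collapse = ", "), call. = FALSE)
  }
  X[cbind(seq_len(n), yi)] <- 1
  sv <- if ("survey" %in% names(newdata)) {
    as.character(newdata$survey)
  } else {
    fit$reference_survey
  }
  if (length(sv) == 1) sv <- rep(sv, n)
  bad <- !sv %in% fit$survey_levels
  if (any(bad)) {
    stop("survey level(s) outside fitted levels: ",
         paste(unique(sv[bad]), collapse = ", "), call. = FALSE)
  }
  for (s in names(fit$survey_cols)) X[sv == s, fit$survey_cols[[s]]] <- 1
  list(X = X, year_i = yi)
}

nearest_knot <- function(knots, x, y) {
  vapply(seq_along(x), function(i) {
    which.min((knots[, 1] - x[i])^2 + (knots[, 2] - y[i])^2)
  }, integer(1))
}

#' Predict expected litter density from a fitted delta model
#'
#' Combined expectation `exp(eta1 + eta2)` (the Poisson-link identity
#' `p * r`), either from fixed effects only (for standardized indices) or
#' including the latent fields at their conditional modes (for maps).
#'
#' @param object A `litter_delta_fit`.
#' @param newdata Data frame with `year` (required), optionally `survey`
#'   (defaults to the reference survey) and, when `include_fields = TRUE`,
#'   `x_km`/`y_km`. Defaults to the fitted hauls.
#' @param include_fields Add the conditional field modes to the linear
#'   predictors?
#' @param ... Unused.
#' @return `newdata` with columns `eta1`, `eta2`, `p` (encounter
#'   probability), `r` (positive rate) and `mean` (expected density,
#'   items per km^2).
#' @export
predict.litter_delta_fit <- function(object, newdata = NULL,
                                     include_fields = FALSE, ...) {
  fit <- object
  newdata <- tibble::as_tibble(newdata %||% fit$data)
  if (!"survey" %in% names(newdata)) newdata$survey <- fit$reference_survey
  des <- build_design(fit, newdata)
  pl <- fit$parlist
  eta1 <- drop(des$X %*% pl$beta1)
  eta2 <- drop(des$X %*% pl$beta2)
  if (include_fields) {
    if (!all(c("x_km", "y_km") %in% names(newdata))) {
      stop("include_fields = TRUE needs x_km and y_km in newdata", call. = FALSE)
    }
    ki <- nearest_knot(fit$knots, newdata$x_km, newdata$y_km)
    ft <- fit$field_types
    if (ft[1] == 1) eta1 <- eta1 + pl$omega[ki, 1]
    if (ft[1] == 2) eta1 <- eta1 + pl$delta1[cbind(ki, des$year_i)]
    if (ft[2] == 1) eta2 <- eta2 + pl$omega[ki, 2]
    if (ft[2] == 2) eta2 <- eta2 + pl$delta2[cbind(ki, des$year_i)]
  }
  link <- poisson_link(eta1, eta2)
  dplyr::bind_cols(newdata, link[c("eta1", "eta2", "p", "r", "mean")])
}

#' Simulate observations from a fitted delta model
#'
#' Draws replicate observation sets at the fitted haul positions with fixed
#' effects at their maximum likelihood estimates and fields at their
#' conditional modes: presence from Bernoulli(p) and positive densities from
#' a Gamma with shape `phi` and mean `r`.
#'
#' @param fit A converged `litter_delta_fit`.
#' @param n_sims Number of replicate datasets.
#' @param seed Optional seed.
#' @return Numeric matrix, hauls x `n_sims`.
#' @export
simulate_from_fit <- function(fit, n_sims = 250L, seed = NULL) {
  stopifnot(inherits(fit, "litter_delta_fit"), n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  pred <- stats::predict(fit, include_fields = any(fit$field_types > 0))
  phi <- exp(fit$parlist$log_phi)
  n <- nrow(pred)
  sims <- matrix(0, n, n_sims)
  for (s in seq_len(n_sims)) {
    pres <- stats::rbinom(n, 1, pred$p) == 1
    ypos <- stats::rgamma(sum(pres), shape = phi, scale = pred$r[pres] / phi)
    col <- numeric(n); col[pres] <- ypos
    sims[, s] <- col
  }
  sims
}

#' Simulated (randomized) quantile residuals
#'
#' Simulation-based residual diagnostics for the delta model: each
#' observation's residual is its randomized empirical-CDF position among
#' `n_sims` simulations from the fitted model, so residuals are standard
#' uniform when the model is consistent with the data. Ties (zeros) are
#' broken uniformly at random, the usual randomized-quantile convention.
#'
#' @inheritParams simulate_from_fit
#' @return Tibble with the haul data plus a `residual` column in (0, 1).
#' @export
quantile_residuals <- function(fit, n_sims = 250L, seed = NULL) {
  if (n_sims < 50) {
    warning("fewer than 50 simulations gives coarse residuals", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate_from_fit(fit, n_sims)
  y <- fit$data$density_per_km2
  res <- vapply(seq_along(y), function(i) {
    n_less <- sum(sims[i, ] < y[i])
    n_eq <- sum(sims[i, ] == y[i])
    (n_less + stats::runif(1) * (n_eq + 1)) / (n_sims + 1)
  }, numeric(1))
  dplyr::mutate(fit$data, residual = res)
}
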