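#' Joint negative log density of data and latent fields
#'
#' Evaluates, in plain R, the joint negative log density that the Laplace
#' approximation integrates: the Bernoulli log-likelihood of presence with
#' Poisson-link probability `p`, the Gamma log-likelihood (shape `phi`, mean
#' `r`) of the positive densities, and the Gaussian log densities of the
#' spatial field and of the AR1 spatiotemporal recursion. Provided as an
#' independent reference computation for the compiled objective (useful for
#' validating the Laplace approximation by importance sampling, and for
#' checking the GLM limit).
#'
#' @inheritParams fit_delta_glmm
#' @param params List with `beta1`, `beta2` (fixed-effect vectors matching
#'   the design built from `hauls`), and, as needed by the structure,
#'   `sigma`, `range`, `angle`, `ratio` (length-2, per component), `rho`
#'   (length-2) and `phi` — all on their natural scales.
#' @param fields List with `omega` (knots x 2 matrix) and/or `delta1`,
#'   `delta2` (knots x years matrices); missing entries default to zero.
#' @return Scalar negative log joint density.
#' @export
joint_neg_log_density <- function(hauls, spec, params, fields = list()) {
  prep <- prepare_delta_data(hauls, spec)
  joint_nll_prepared(prep, spec, params, fields)
}

# log N(x; mu, Sigma) via Cholesky
dmvnorm_log <- function(x, Sigma, mu = 0) {
  L <- chol(Sigma)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(L))) - length(x) / 2 * log(2 * pi)
}

joint_nll_prepared <- function(prep, spec, params, fields) {
  ft <- c(field_code(spec$binomial), field_code(spec$gamma))
  K <- nrow(prep$knots); T_ <- length(prep$years)
  omega <- fields$omega %||% matrix(0, K, 2)
  delta <- list(fields$delta1 %||% matrix(0, K, T_),
                fields$delta2 %||% matrix(0, K, T_))
  if (params$phi <= 0) stop("Gamma shape phi must be positive", call. = FALSE)

  nll <- 0
  for (c in 1:2) {
    if (ft[c] == 0) next
    Sigma <- matern_aniso_cov(prep$knots, params$sigma[c], params$range[c],
                              (params$angle %||% c(0, 0))[c],
                              (params$ratio %||% c(1, 1))[c])
    if (ft[c] == 1) {
      nll <- nll - dmvnorm_log(omega[, c], Sigma)
    } else {
      rho <- params$rho[c]
      d <- delta[[c]]
      nll <- nll - dmvnorm_log(d[, 1], Sigma)
      if (T_ > 1) {
        for (t in 2:T_) {
          nll <- nll - dmvnorm_log(d[, t] - rho * d[, t - 1],
                                   (1 - rho^2) * Sigma)
        }
      }
    }
  }

  X <- unname(prep$X)
  eta1 <- drop(X %*% params$beta1)
  eta2 <- drop(X %*% params$beta2)
  ki <- prep$knot_i; yi <- prep$year_i
  if (ft[1] == 1) eta1 <- eta1 + omega[ki, 1]
  if (ft[1] == 2) eta1 <- eta1 + delta[[1]][cbind(ki, yi)]
  if (ft[2] == 1) eta2 <- eta2 + omega[ki, 2]
  if (ft[2] == 2) eta2 <- eta2 + delta[[2]][cbind(ki, yi)]

  y <- prep$hauls$density_per_km2
  n_grp <- exp(eta1)
  log_p <- log(-expm1(-n_grp))
  zero <- y == 0
  nll <- nll - sum(-n_grp[zero])                       # log(1 - p)
  log_r <- eta1 + eta2 - log_p
  nll <- nll - sum(log_p[!zero]) -
    sum(stats::dgamma(y[!zero], shape = params$phi,
                      scale = exp(log_r[!zero]) / params$phi, log = TRUE))
  nll
}
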