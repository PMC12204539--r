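#' Anisotropic Matern covariance matrix
#'
#' Matern covariance with smoothness nu = 1 between planar locations, after a
#' geometric-anisotropy transform: coordinates are rotated by `-angle` and the
#' axis aligned with `angle` is shrunk by `ratio`, so spatial correlation
#' persists `ratio` times further along the `angle` direction than across it.
#' With `kappa = sqrt(8) / range`, the correlation at transformed distance `h`
#' is `(kappa h) K_1(kappa h)` and equals ~0.1 at `h = range` (the standard
#' "range where correlation becomes negligible" convention for this family).
#'
#' @param locations Two-column matrix or data frame of planar coordinates
#'   (km), one row per location.
#' @param sigma Marginal standard deviation (> 0).
#' @param range Correlation range (km, > 0) across the minor axis.
#' @param angle Anisotropy rotation angle in radians (direction of the long
#'   axis); ignored when `ratio = 1`.
#' @param ratio Anisotropy stretch ratio (>= 1); `1` is isotropy.
#' @return Symmetric positive semi-definite covariance matrix with
#'   `sigma^2` on the diagonal.
#' @export
matern_aniso_cov <- function(locations, sigma, range, angle = 0, ratio = 1) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 2, sigma > 0, range > 0, ratio >= 1)
  if (!all(is.finite(locations))) stop("non-finite coordinates", call. = FALSE)
  # rotate into the anisotropy frame (by -angle), shrink the long axis
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)),
                2, 2, byrow = TRUE)
  u <- locations %*% t(rot)
  u[, 1] <- u[, 1] / ratio
  d <- as.matrix(stats::dist(u))
  kappa <- sqrt(8) / range
  C <- matern1_corr(kappa * d)
  sigma^2 * C
}

# Matern correlation with nu = 1: x K_1(x), continuously extended to 1 at 0.
matern1_corr <- function(x) {
  out <- matrix(1, nrow(x), ncol(x))
  pos <- x > 0
  out[pos] <- x[pos] * besselK(x[pos], 1)
  out
}

# MVN sampler via Cholesky with a small diagonal jitter for near-singular
# covariances (e.g. nearly coincident locations).
rmvn_chol <- function(n, Sigma, jitter = 1e-10) {
  p <- nrow(Sigma)
  L <- chol(Sigma + diag(jitter * mean(diag(Sigma)) + 1e-300, p))
  matrix(stats::rnorm(n * p), n, p) %*% L
}

#' Simulate spatial and AR1 spatiotemporal Gaussian fields
#'
#' Draws a time-constant spatial field `omega ~ MVN(0, Sigma)` and/or a
#' spatiotemporal field following the stationary AR1 recursion
#' `delta_1 ~ MVN(0, Sigma)`, `delta_t = rho delta_{t-1} +
#' sqrt(1 - rho^2) eps_t` with `eps_t ~ MVN(0, Sigma)`, so the marginal
#' covariance of every `delta_t` is `Sigma`.
#'
#' @inheritParams matern_aniso_cov
#' @param n_years Number of years for the spatiotemporal field.
#' @param rho AR1 correlation between consecutive yearly fields, in (-1, 1).
#' @return A list with `omega` (numeric vector, one value per location) and
#'   `delta` (matrix locations x years).
#' @export
simulate_fields <- function(locations, sigma, range, angle = 0, ratio = 1,
                            n_years = 1L, rho = 0) {
  if (abs(rho) >= 1) stop("AR1 coefficient must satisfy |rho| < 1", call. = FALSE)
  n <- nrow(as.matrix(locations))
  if (sigma == 0) {
    return(list(omega = numeric(n), delta = matrix(0, n, n_years)))
  }
  Sigma <- matern_aniso_cov(locations, sigma, range, angle, ratio)
  omega <- drop(rmvn_chol(1, Sigma))
  delta <- matrix(0, n, n_years)
  eps <- rmvn_chol(n_years, Sigma)
  delta[, 1] <- eps[1, ]
  if (n_years > 1) {
    for (t in 2:n_years) {
      delta[, t] <- rho * delta[, t - 1] + sqrt(1 - rho^2) * eps[t, ]
    }
  }
  list(omega = omega, delta = delta)
}
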