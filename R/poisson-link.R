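#' Poisson-link transform for delta models
#'
#' Maps the two log-linear predictors of a Poisson-link delta model to the
#' encounter probability and the positive-catch rate. With group density
#' `n = exp(eta1)` and weight-per-group `w = exp(eta2)`:
#' encounter probability `p = 1 - exp(-n)` (a complementary log-log inverse
#' link) and positive rate `r = n w / p`, so that the unconditional mean
#' satisfies `p * r = n * w = exp(eta1 + eta2)` exactly. Computed in log
#' space to avoid overflow.
#'
#' @param eta1,eta2 Linear predictors (vectors of equal length recycled the
#'   usual way).
#' @return A tibble with columns `eta1`, `eta2`, `n`, `w`, `p`, `r` and the
#'   unconditional `mean` = `p * r`.
#' @examples
#' poisson_link(0, 0) # p = 1 - exp(-1), r = 1/p, mean 1
#' @export
poisson_link <- function(eta1, eta2) {
  stopifnot(all(is.finite(eta1)), all(is.finite(eta2)))
  n <- exp(eta1)
  # log p = log(1 - exp(-n)), stable for tiny and huge n
  log_p <- log(-expm1(-n))
  log_r <- eta1 + eta2 - log_p
  tibble::tibble(eta1 = eta1, eta2 = eta2, n = n, w = exp(eta2),
                 p = exp(log_p), r = exp(log_r), mean = exp(eta1 + eta2))
}
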