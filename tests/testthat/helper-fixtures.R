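# Shared synthetic fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# Single-survey truth with all latent fields and gradients off: the GLM
# limit of the generative model (saturated year design).
glm_truth <- function(seed = 5L) {
  truth_config(
    years = 2016:2019, hauls_per_year = c(IBTS = 40L),
    year_effect_binomial = c(-0.2, 0.1, -0.4, 0.3),
    year_effect_gamma = c(3.5, 3.2, 3.8, 3.0),
    shore_gradient = c(0, 0), sigma_spatial = c(0, 0), sigma_st = c(0, 0),
    phi = 1, seed = seed
  )
}

test_glm_hauls <- function() cached("glm_hauls", gen_hauls(glm_truth()))

test_glm_fit <- function() {
  cached("glm_fit", fit_delta_glmm(
    test_glm_hauls(), delta_spec(binomial = "none", gamma = "none")
  ))
}

# Small two-survey dataset with spatial + AR1 structure, and a fit with
# fields in both components, for prediction/index/residual tests.
field_truth <- function(seed = 10L) {
  truth_config(
    years = 2017:2021, hauls_per_year = c(IBTS = 30L, CTS = 25L),
    sigma_spatial = c(0.6, 0), sigma_st = c(0, 0.6), rho = c(0, 0.6),
    phi = 1, seed = seed
  )
}

test_field_hauls <- function() cached("field_hauls", gen_hauls(field_truth()))

test_field_fit <- function() {
  cached("field_fit", fit_delta_glmm(
    test_field_hauls(),
    delta_spec(binomial = "spatial", gamma = "st_ar1", n_knots = 15L)
  ))
}
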