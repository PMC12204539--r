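---
title: "Models and methods behind litterindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind litterindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`litterindex` addresses two linked questions in seafloor-litter monitoring
on a trawled shelf:

1. **Can a small-footprint underwater video (UWTV) survey detect litter at
   realistic densities?** A 10-minute video tow sweeps roughly 148 m² —
   about 1/468th of a 30-minute bottom-trawl haul — so at tens of items per
   km² most transects see nothing.
2. **What are the standardized annual litter densities and the trend when
   coastal and offshore trawl surveys are combined?** The two surveys have
   different gears and different, partially overlapping footprints over a
   strong shore-to-offshore density gradient, so raw means are not
   comparable; a geostatistical model-based index is.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where reasonable alternatives
existed. It quotes no empirical results beyond what the package's own test
suite and acceptance script compute.

## 1. The transect-sampling detection experiment

The simulation world is a 1000 × 1000 m grid of 1 m² cells (`place_litter()`).
A density scenario of $D$ items per km² puts exactly
$\mathrm{round}(D \cdot \text{area}_{km^2})$ items on distinct cells, uniformly
at random — density scenarios are treated as exact totals, not Poisson draws,
because the experiment asks "what would a survey see in a patch that truly
holds $D$ items". A UWTV transect (`draw_transect()`) is a run of 148
consecutive cells, horizontal or vertical with probability ½ each, start
position uniform over placements that keep the transect fully inside the grid
(no wrap-around or clipping; at 148/1000 the edge exclusion is negligible).
Transects within a replicate are drawn independently and may overlap.

A replicate (`run_replicate()`) places a fresh litter field and `n` transects,
and `run_experiment()` crosses the density scenarios
{10, 50, 100, 500, 1000, 5000} per km² with sample sizes
{50, 100, 200, 500, 1000}, 1000 replicates each, recording the proportion of
replicates that capture zero items and the mean of the replicate density
estimates. Densities are estimated by pooled swept area
(`estimate_density()`): total items over total area swept, identical to the
mean of per-transect densities when transects share a length. One item in a
single 148 m² transect is 1/148e-6 ≈ 6757 items per km², which is why single
detections produce wildly overdispersed replicate estimates at low density.

Two design choices deserve a note:

* **Field regeneration.** A fresh field per replicate is the default
  (`regenerate_field_per_replicate = TRUE`): each replicate is then an
  independent draw of both the world and the survey, and the zero-capture
  proportion estimates a single well-defined probability. Sharing one field
  per scenario is available as a flag for studying survey-only variability.
* **RNG discipline.** Each (density, sample size) cell derives its seed
  deterministically from the experiment seed, so results for a scenario do
  not depend on which other scenarios are in the grid.

### The closed-form companion

For $n$ *disjoint* transects of area $a$ on a grid of area $A$ holding $D$
uniform items, the probability that the survey captures nothing is

$$P(\text{none}) = \left(1 - \frac{na}{A}\right)^{D},$$

implemented as `prob_none_detected()`. Real transects may overlap, which
makes the true zero-capture probability slightly *larger* than this bound;
the union of $n$ random transects covers about $A(1 - e^{-na/A})$ in
expectation, so the discrepancy is only material at the most extreme
scenario (1000 transects, coverage 14.8%), where it is still within the
Monte-Carlo noise of a 1000-replicate experiment. The test suite checks the
simulator against this closed form over the full default grid at exactly
that tolerance (3 binomial standard errors).

## 2. Zero-event statistics

When all $n$ transects come back empty, the data still bound the
per-transect presence probability:

* **Rule of three** (`rule_of_three()`): upper 95% bound $3/n$, upper 99%
  bound $4.61/n$. The constants are $-\log\alpha$ rounded as conventionally
  printed (2.996 → 3, 4.605 → 4.61); they are deliberately *not* recomputed,
  so the package reproduces the published convention digit for digit. The
  approximation tracks the exact zero-success Clopper–Pearson bound
  $1 - \alpha^{1/n}$ to within ~3% at $n = 50$ and under 2% from
  $n \approx 100$; it is intended for $n > 30$ and warns below that.
* **Agresti–Coull** (`agresti_coull_ci()`): the adjusted-Wald interval with
  pseudo-counts $z^2/2$, for exploring scenarios where a few transects do
  contain litter. Bounds are clamped to [0, 1]. For zero successes its upper
  bound sits ~40–55% above $3/n$ across realistic $n$ — the two methods are
  companions, not substitutes.
* **Density translation** (`upper_density_bound()`): if the upper-bound
  fraction of transects each held exactly one item, the survey-mean density
  would be $\text{upper} \times 10^6/a$ items per km². For 87 all-zero
  transects of 148 m² this is $(3/87)(10^6/148) \approx 233$ items per km² —
  a bookkeeping identity, not an estimate, and a simplification in that a
  transect could hold more than one item.

## 3. The geostatistical Poisson-link delta model

Observed haul densities $y_{s,t}$ (items per km² at location $s$, year $t$)
are zero-inflated and continuous, so the model is a two-part (hurdle) GLMM:
a binomial component for presence and a Gamma component for the positive
densities, linked through the Poisson-link parameterization. Each component
$c \in \{1, 2\}$ has a linear predictor

$$\eta_c(s,t) = X_{s,t}\beta_c + \omega_c(s) \;\text{or}\; \delta_{c,t}(s),$$

with year entering as a factor (independent intercepts — litter is assumed
replaced and added every year, the standard index-standardization
assumption) and survey as a categorical catchability contrast against a
reference survey. Each component carries **one** latent Gaussian field:

* `spatial`: $\omega \sim \mathrm{MVN}(0, \Sigma)$, constant over time;
* `st_ar1`: yearly fields with stationary AR1 dependence,
  $\delta_1 \sim \mathrm{MVN}(0, \Sigma)$,
  $\delta_t = \rho\,\delta_{t-1} + \sqrt{1-\rho^2}\,\epsilon_t$,
  $\epsilon_t \sim \mathrm{MVN}(0, \Sigma)$, so every year's marginal
  covariance is exactly $\Sigma$;
* `none`: the GLM limit.

The three candidate structures compared by marginal AIC are
spatial/spatial, st_ar1/st_ar1 and spatial/st_ar1 (binomial/Gamma). The
fixed-effect vectors $\beta_1, \beta_2$ are separate per component — the
standard delta-model practice; sharing them across components has no
precedent in this model family and would couple catchability across
processes with different mechanisms.

**Poisson link.** With group density $n = e^{\eta_1}$ and weight
$w = e^{\eta_2}$:

$$p = 1 - e^{-n}, \qquad r = \frac{n w}{p}, \qquad p \, r = e^{\eta_1 + \eta_2}.$$

Presence is Bernoulli($p$) (a complementary log-log inverse link), positive
density is Gamma with shape $\phi$ and mean $r$ (variance $r^2/\phi$), and
the unconditional mean is exactly $e^{\eta_1+\eta_2}$ — the identity that
makes index extraction trivial and removes the independence assumption of
the classical delta model. All computations are done in log space
(`log p = log(-expm1(-n))`) so extreme predictors cannot overflow.

**Matérn covariance and anisotropy.** $\Sigma$ is Matérn with smoothness
$\nu = 1$ (fixed, the usual convention for this model family, not
estimated): $\mathrm{cor}(h) = (\kappa h) K_1(\kappa h)$ with
$\kappa = \sqrt{8}/\text{range}$, giving correlation
$\sqrt{8} K_1(\sqrt 8) \approx 0.14$ at $h = \text{range}$ — the
conventional "distance at which correlation becomes negligible". Geometric
anisotropy rotates coordinates by the anisotropy angle and shrinks the
rotated first axis by the stretch ratio ≥ 1, so correlation persists
`ratio` times further along the angle direction (alongshore, in the
motivating application) than across it. At ratio = 1 the likelihood is
exactly invariant to the angle, so anisotropy estimation is opt-in
(`delta_spec(anisotropy = TRUE)`); fitting an angle with the ratio pinned at
1 would leave a flat direction in the Hessian.

**Knots instead of a mesh.** Fields are evaluated at `n_knots` k-means
centres of the haul positions (deterministically seeded), and each haul
reads the field at its nearest knot. At desk scale (tens of knots, hundreds
of hauls) dense Matérn linear algebra at the knots is simpler and more
transparent than a triangulated-mesh SPDE approximation, and removes the
mesh-construction degrees of freedom; the cost is a piecewise-constant
field. When hauls revisit fixed stations and `n_knots` is at least the
station count, the knots coincide with the stations and the projection is
exact.

**Estimation.** The fields are integrated out by the Laplace approximation
(exact inner Newton optimization over field values and the log-determinant
of the inner Hessian), and `stats::nlminb` maximizes the marginal
likelihood over fixed effects and hyperparameters with exact
automatic-differentiation gradients from the compiled objective. Variances
are log-transformed, the AR1 coefficient uses a scaled logit onto (−1, 1),
and the Gamma shape is log-transformed. The accuracy of the Laplace
approximation is itself validated in the test suite against a
100,000-sample importance-sampling estimate of the true marginal likelihood
on a 6-location, 2-year instance (agreement required within 0.5 log-units),
and the no-field limit is required to match independent cloglog-binomial
and log-Gamma GLMs to 10⁻³.

**Convergence diagnostics** are computed, never assumed: positive-definite
Hessian of the outer parameters, maximum absolute marginal-likelihood
gradient below 10⁻³, and a configurable flag for implausibly large
field-hyperparameter standard errors (`field_sd_threshold`, default 10 on
the estimation scale). The published criterion this last check descends
from is ambiguous as printed, so the threshold is explicit configuration
rather than a guessed constant. Failed checks warn and are recorded in the
fit object.

**Marginal AIC** is $2k - 2\log L$ with $k$ counting fixed effects and
hyperparameters only (the likelihood is marginal, fields integrated out);
`select_model()` refuses to compare fits on different data.

**Model residuals** (`quantile_residuals()`) are simulation-based
randomized-quantile (PIT) residuals: each observation's randomized
empirical-CDF position among `n_sims` simulations from the fitted model,
with fields held at their conditional modes; uniform when the model is
consistent with the data. Ties at zero are broken uniformly, the standard
randomized-quantile convention for the point mass.

Two data rules are enforced rather than silently absorbed: every year in
the modelled span needs at least one haul (the AR1 field can bridge sparse
years, but a wholly unobserved year would leave its fixed effect
likelihood-free), and a survey level with no positive observations is
excluded from fitting with a message — its catchability contrast and Gamma
component would be unidentifiable, which is exactly the situation of an
all-zero video survey.

## 4. Annual indices and the CV-weighted trend

The standardized index for year $y$ is the fixed-effects-only prediction at
the reference survey, $\widehat{I}_y = \exp(\hat\beta_{1,y} +
\hat\beta_{2,y})$ — "conditional on year, omitting the random effects".
Uncertainty comes from the joint fixed-effect covariance either by the delta
method on the log scale (Wald interval
$\exp(\log\widehat I_y \pm z\,\mathrm{se}_{\log})$, the default) or by
simulating parameter vectors from the estimated covariance
(`method = "sim"`); whether published intervals of this kind are Wald or
simulation-based is usually unstated, so both are provided and are checked
against each other in the tests.

The trend (`weighted_trend()`) is a weighted least-squares regression of
the index on year with weights $1/\mathrm{CV}_y$ — the inverse coefficient
of variation, exactly as the motivating analysis specifies, *not* the
inverse squared CV that inverse-relative-variance weighting would suggest;
the latter is available via `weights = "inverse_cv2"`. The slope interval
uses the t distribution with $n_{\text{years}} - 2$ degrees of freedom. A
penalized-spline smoother of the annual estimates is a plotting aid in the
source material and is deliberately out of scope; the linear slope is the
inferential quantity.

## 5. The synthetic-data generator

`truth_config()` + `gen_hauls()` generate haul data with the statistical
structure the model assumes, so every downstream stage is testable without
any real data:

* **Geometry.** A 200 × 100 km planar shelf; `y_km` is distance offshore.
  The coastal survey (CTS, ~30 hauls/year) works the strip `y ≤ 25` km, the
  offshore survey (IBTS, ~40 hauls/year) a box `y ≥ 15` km: partially
  overlapping footprints, as in the motivating case study. Positions are
  uniform within footprints, redrawn yearly by default; `fixed_stations =
  TRUE` reuses station positions across years.
* **Observation model.** Exactly the Poisson-link delta model of Section 3,
  applied generatively, with a linear shore-distance gradient added to both
  predictors. The gradient is a *fixed* term (centred at 40 km) rather than
  an extra latent field: the motivating analysis attributes the
  shore-to-offshore pattern to its latent fields, but a fixed term makes the
  truth exactly recoverable and the generator testable.
* **Defaults.** Years 2012–2024; true survey effect 0 in both components (so
  any between-survey difference in raw means is purely spatial — the
  pattern the index model exists to disentangle); Gamma year effects tracing
  a slow decline with mean combined index ≈ 34 items/km²; field SDs 0.4–0.6;
  range 30 km; anisotropy ratio 2 alongshore; AR1 ρ = 0.95 (binomial) and
  0.75 (Gamma); Gamma shape 1. The binomial ρ is set at 0.95 rather than the
  0.99 magnitude reported for real data: over a 13-year span a ρ of 0.99 is
  observationally indistinguishable from a constant field, which would make
  the generator's own consumer test (recovering ρ) ill-posed.
* **Video campaigns.** `gen_uwtv_campaign()` places transects in the
  offshore footprint and draws per-transect counts as Poisson with mean
  (local density × 148e-6) — the thinned-point-process limit of the grid
  experiment, appropriate for studying the probability that an entire
  campaign returns empty.

What the generator does **not** emulate: coastline geometry and bathymetry,
litter-category composition, covariate-driven density (vessel traffic,
currents), spatially varying catchability, and preferential sampling.
Passing tests therefore demonstrate correctness of the estimation machinery
under the model's own assumptions, not robustness to the ways real survey
data violate them.

## 6. Problem sizes, tolerances, and reproducibility

The validation experiments in the test suite use sizes chosen to exercise
the methods meaningfully while keeping a full run comfortable on a laptop:
the parameter-recovery study fits 50 replicate surveys of 13 years × 40
fixed stations (Wald coverage of every field hyperparameter required ≥ 85%
at the 95% level); the AIC-selection study uses 20 replicates of 6 years ×
30 stations fitted under all three candidate structures; the
Laplace-vs-importance-sampling check uses 6 locations × 2 years with 10⁵
draws; Monte-Carlo assertions use 3-standard-error bands throughout.
Covariance factorizations add a relative diagonal jitter of 1e-10 before
Cholesky to tolerate nearly coincident locations.

All randomness flows from explicit seeds: experiment seeds derive
per-scenario streams, generator seeds are stored in the truth configuration
(regeneration is bit-identical), k-means knot placement is seeded, and
`run_litter_pipeline()` records every seed in its manifest.

## Known limitations

* When the data contain a strong time-constant spatial signal (such as a
  persistent shore gradient) and a component carries only an AR1
  spatiotemporal field, the estimated ρ is pushed toward 1 and the range
  grows large: the yearly fields collapse toward one shared surface whose
  level trades off against the year intercepts, widening the annual index
  intervals. This mirrors the near-unit ρ estimates reported for real
  litter data. It is a property of the data/model combination, not an
  estimation failure; comparing against the spatial-field candidate by AIC
  and estimating anisotropy usually stabilizes such fits.
* The knot projection is piecewise-constant; with few knots and long-range
  fields, field variance is mildly attenuated relative to the
  exact-location model. Use more knots (or fixed stations) when the spatial
  signal is the quantity of interest.
* Dense covariance algebra scales cubically in knots and years × knots;
  the intended regime is tens of knots, not thousands of mesh vertices.
* The closed-form zero-capture probability assumes disjoint transects;
  at very high transect counts it is a slight underestimate of the
  simulator's truth.
* Indices are fixed-effects-only at a reference survey; area-weighted
  integration over a prediction grid is out of scope.
* `lonlat_to_km()` is a single equirectangular approximation for regional
  domains, not a cartographic projection.
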