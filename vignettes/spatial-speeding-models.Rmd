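---
title: "Bayesian hierarchical spatial count models for GPS speeding events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian hierarchical spatial count models for GPS speeding events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedcount)
```

## The problem

Urban speeding frequency varies across road segments for two kinds of
reasons: measurable road characteristics (posted limit, lane count, cross
section, special lanes, work zones, segment length) and spatial structure
that those covariates do not capture. `speedcount` implements the complete
chain from raw vehicle GPS trajectories to per-segment counts of *total*
and *serious* speeding events, and fits four Bayesian hierarchical count
models to those counts: Poisson and negative-binomial log-linear models,
each with and without Besag–York–Mollié (BYM) spatial effects. The model
abbreviations used throughout are BHPLM, BHNBLM, BHSPLM and BHSNBLM
(Bayesian hierarchical (spatial) Poisson / negative-binomial log-linear
model).

## Event extraction

A GPS record stream (vehicle, timestamp, longitude, latitude) is processed
per vehicle:

1. **Map matching.** Each point is matched to the nearest road centerline
   by planar distance under a local equirectangular projection, using a
   grid spatial index with 100 m cells; points farther than one cell from
   every centerline stay unmatched. "Nearest centerline" distance is a
   deliberate simplification (the field calls this point-to-polyline or
   "adjusted Euclidean" matching); probabilistic or HMM matching is out of
   scope. Exact distance ties resolve to the lower segment id.
2. **Intersection exclusion.** Points strictly closer than 30 m to any
   intersection are suspended (intersection speed limits are ambiguous);
   a point at exactly 30 m is retained. A nanometre of slack absorbs the
   degree-projection round-trip.
3. **Anomaly screening.** A point pair is discarded when the heading turns
   by more than 150° relative to the previous displacement (U-turn proxy)
   or opposes its matched segment's orientation by more than 150°
   (wrong-way proxy). The screened behaviours are part of the protocol;
   the 150° threshold is this package's configurable operationalization.
4. **Pairwise speed and classification.** The average speed of adjacent
   points is the travelled distance over the elapsed time,
   `v = 3.6 * dD / dT` km/h. A pair is *speeding* when `v` strictly
   exceeds the posted limit and *serious* when it strictly exceeds 1.2
   times the limit (the legal criterion of 20% over). Boundary speeds
   (`v == limit`, `v == 1.2 * limit`) do not qualify — "exceeds" is read
   strictly, and the boundary behaviour is pinned by tests.
5. **Event merging.** Maximal runs of consecutive valid speeding pairs
   merge into one complete event; an isolated speeding pair is itself an
   event. Serious runs are merged independently, so a serious event also
   contributes to the total class. Excluded, unmatched or anomalous pairs
   break runs — a suspended point cannot serve as evidence joining two
   events. Events spanning a segment boundary are attributed to the
   segment of their first pair (deterministic and order-independent; the
   attribution rule is not dictated by the protocol).

Counts are aggregated per segment into `y_total` and `y_serious`, the two
outcomes modelled below. A variance-inflation-factor helper (`vif()`)
reproduces the usual collinearity diagnostic for the covariate table.

## The four models

For segment `s = 1..S` with covariates `X_ks` (`k = 1..m`):

* **Data layer.** `Y_s ~ Poisson(lambda_s)`, or negative binomial with
  `p_s = r_s / (lambda_s + r_s)`, i.e. mean `lambda_s` and variance
  `lambda_s (1 + lambda_s / r_s)`; `r_s` is the per-segment dispersion.
* **Process layer.** `log(lambda_s) = a0 + sum_k X_ks beta_k`
  (+ `mu_s + v_s` in the spatial variants). `mu` is the spatially
  correlated effect with an intrinsic CAR (ICAR) prior — conditionally
  normal around the mean of its neighbours with variance
  `sigma_mu2 / n_neighbours` — and `v` is iid `N(0, sigma_v2)`
  heterogeneity (the BYM decomposition). The binary spatial weights are
  shared-endpoint adjacency of road segments; any user-supplied symmetric
  0/1 matrix is accepted, since adjacency conventions for road networks
  vary.
* **Parameter layer.** `beta_k ~ N(0, 10000)`, `a0 ~ N(0, 10000)`,
  `sigma_mu2, sigma_v2 ~ InverseGamma(0.5, 0.00005)` (read literally as a
  prior on the variances; the equivalent precision-Gamma reading used by
  BUGS-family software is the same distribution), and
  `r_s ~ Gamma(shape 5, rate 0.5)` independently per segment. A shared-`r`
  variant is available (`model_spec(..., shared_r = TRUE)`) because both
  conventions appear in this literature.

The improper ICAR prior is used through its pairwise-difference kernel
with rank deficiency equal to the number of connected components `G`;
`mu` is identified by a sum-to-zero convention per component.

## Sampler design

Fitting is Metropolis-within-Gibbs (`fit_model()`), with the inner loop in
C++:

* **Coefficients.** `(beta, a0)` move as one multivariate random-walk
  Metropolis block whose proposal covariance comes from the Fisher
  information of a weighted least-squares fit of `log(y + 0.5)`; a scalar
  scale adapts during burn-in. One-coordinate-at-a-time updates are
  hopeless here: with event counts in the hundreds-to-thousands per
  segment the likelihood is extremely sharp and strongly correlated across
  coefficients.
* **Spatial effects.** Each `mu_s` updates by MH against its local
  likelihood times the ICAR full conditional; each `v_s` against its
  likelihood times `N(0, sigma_v2)`; per-element scales adapt.
* **Likelihood-neutral moves.** Because the likelihood pins only the sum
  `mu_s + v_s`, two extra move families keep the weakly identified
  directions mixing: an exchange `(mu_s + d, v_s - d)` and a coefficient
  analogue `(beta_k + d, v - X_k d)` (similarly for `a0`), both leaving
  the linear predictor unchanged and accepted on prior ratios alone; and
  an interweaving rescale `(mu, sigma_mu2) -> (c mu, c^2 sigma_mu2)` with
  `v` absorbing the difference, which jumps between the collapsed
  (`mu ~ 0`) and smooth-field posterior modes that single-site updates
  cannot travel between. Without these moves the variance chains stall for
  exactly the reasons the spatial-confounding literature describes.
* **Variances.** `sigma_mu2 | mu ~ InvGamma(q0 + (S - G)/2,
  rho0 + quad/2)` and `sigma_v2 | v ~ InvGamma(x0 + S/2, z0 + sum v^2/2)`
  are drawn exactly (conjugacy); `quad` is the ICAR pairwise quadratic
  form.
* **Dispersion.** Each `r_s` updates by random walk on `log r_s` with the
  Jacobian correction.
* **Recentring.** After every spatial sweep `mu` is recentred to sum to
  zero per component with the global mean absorbed into `a0`; on a
  connected graph (the generator's and the intended use case) the linear
  predictor is exactly invariant, which a test checks to 1e-10 via the
  stored deviances. On a multi-component graph the per-component residual
  means make the projection approximate for `a0` only.
* **Adaptation and initial values.** All proposal scales adapt toward a
  0.35 acceptance rate during burn-in only, so the post-burn-in kernel
  leaves the posterior invariant. Chains start from the weighted
  least-squares coefficient centre plus noise drawn at 5 times the
  Fisher-information scale — overdispersed relative to the posterior, which
  is what the Gelman–Rubin diagnostic needs. Dispersing inits at the prior
  scale (sd 100 per coefficient) is unusable with a log link: a few units
  of noise on the length coefficient alone puts `exp(eta)` beyond
  floating-point range. Starts with a non-finite posterior or `|eta| > 50`
  are redrawn (up to 100 times).

Two chains of 20,000 iterations with 5,000 burn-in are the default
(`mcmc_config()`); they complete in seconds at `S = 100`–256 and give
maximum PSRF values of about 1.01–1.03 on data generated from the model.
The long two-chain protocol of 400,000 iterations with 100,000 burn-in is
one switch away (`paper_scale = TRUE`); it changes run time, not
correctness, and the desk scale is what the tests and the acceptance
script exercise.

## Assessment

`summarize_posterior()` reports posterior means, standard deviations and
equal-tailed 95% credible intervals pooled across chains; a covariate is
declared significant when its interval excludes zero (the credible-interval
operationalization of "p < 0.05" — these are interval statements, not
p-values). `select_significant()` performs backward elimination: refit
after dropping the most centrally-zero covariate (smallest `|mean|/sd`)
until all remaining intervals exclude zero. The one-at-a-time backward
rule is a design choice; published coefficient tables in this literature
show different retained sets per model without stating a procedure.

`dic()` computes `D-bar` as the mean of per-draw deviances (stored during
sampling, constants included) and `D(theta-bar)` by plugging in the
posterior means of *all* stochastic quantities, including the random
effects and dispersions — the convention of BUGS-family software, which
makes `p_d` reflect the effective number of parameters absorbed by the
random effects. `compare_models()` ranks by DIC with the usual 5-point
equivalence rule. `spatial_fraction()` reports
`sigma_mu2 / (sigma_mu2 + sigma_v2)` both per draw (with an interval) and
as the point fraction of the posterior-mean variances — the latter is the
number a table of posterior means implies.

## The synthetic-data generator

No real taxi GPS data ship with the package, so every stage is validated
on synthetic data with known ground truth.

* **Network.** `generate_road_network()` lays a rectilinear planar
  spine-and-branch ("comb") layout: an arterial divided into segments at
  junctions, with perpendicular branches on alternating sides. Adjacency
  is shared-endpoint; the graph is connected; junction nodes touched by
  two or more segments are the intersections. Each segment's length is an
  independent draw from a normal with mean 162.4 m and s.d. 88.6 m
  truncated to [40, 489.948] m, inside the observed study range of
  4.386–489.948 m. Two geometric guarantees motivated this layout over a
  shared-spacing grid: parallel centerlines never come closer than 40 m
  (twice the 20 m jitter bound, keeping map matching solvable), and
  lengths are independent across segments. On a rigid grid all parallel
  segments in the same gap share one length, which pushes the length
  covariate into the space of smooth spatial fields and artificially
  degrades its identifiability under the BYM prior — a generator artifact
  real road networks do not share.
* **Covariates.** Eight binary indicators are Bernoulli draws at the study
  marginals (speed-limit indicator 0.21, lanes 0.231, cross-section 0.555,
  one-way 0.043, non-motorized lane 0.891, bus lane 0.625, viaduct/tunnel
  0.090, work zone 0.102); the speed-camera count is Binomial(4, 0.15625)
  (mean 0.625, matching its 0–4 range); length is copied from the
  geometry. The speed-limit indicator and the posted limit are generated
  consistently (40 km/h when the indicator is 1, 60 km/h otherwise,
  reflecting the dominance of 60 km/h limits on the arterials studied).
* **Spatial effects and counts.** `sample_spatial_effects()` draws `mu`
  exactly from the ICAR joint density restricted to the sum-to-zero
  subspace via eigendecomposition of `D - W` (exact and fast for a few
  thousand segments), and `v` iid normal. `simulate_counts()` applies the
  log link and draws Poisson or negative-binomial counts.
  `default_truth()` carries the study conditions: the posterior-mean
  coefficients of the spatial Poisson fits (total outcome: intercept
  4.667, variances 0.017/0.038; serious outcome: intercept 2.348,
  variances 0.013/0.036), completed with companion values for covariates
  a given table dropped.
* **Trajectories.** `simulate_trajectories()` emits GPS points along
  centerlines at a 10 s interval. Physics fixes a constraint: at 10 s
  sampling an above-limit pair spans at least 111 m (40 km/h limit), so a
  planted episode fits only on segments where that pair stays 55 m clear
  of both endpoints (outside the 30 m intersection buffer plus the 20 m
  jitter bound). Each episode therefore rides its own short vehicle
  trajectory — one above-limit pair, flanked by below-limit points when
  the segment is long enough — and `plan_episodes()` only plants on
  feasible segments. Planted speeds are fractions of the limit (0.75
  cruise, 1.10 total, 1.35 serious) whose margins are many standard
  deviations wide relative to the default 2 m positional jitter
  (truncated at 20 m), so extraction recovers the planted per-segment
  counts *exactly* — the end-to-end test asserts identity, not
  approximation.

What passing these tests shows — and what it does not: the pipeline
recovers exactly what was planted under controlled geometry and noise, and
the samplers target the stated posteriors. Real GPS data add multipath
error far beyond isotropic jitter, irregular sampling, congestion-induced
speed profiles, and map errors; none of those are emulated, and the
trajectory channel cannot produce the hundreds of events per segment that
two weeks of city-wide taxi data produce. For that reason the pipeline's
synthetic mode fits the models to counts simulated from the count models
themselves (the generative conditions above) while using the trajectory
channel to verify extraction exactly; in files mode the models are fitted
to whatever the extraction yields.

## Numerical choices and limitations

* Strict inequalities at both classification thresholds; `1.2 * limit` is
  exact in floating point for the limits in use (40, 60 km/h), and the
  boundary tests would catch a platform where it is not.
* The equirectangular projection about the network centroid is accurate to
  well under 0.1% against a haversine oracle over a ~10 km window.
* Grid-index registration is by bounding box of each polyline piece — a
  superset of the cells truly crossed, so candidates can only be added,
  never lost; matching filters candidates by true distance afterwards.
* **Weak identification of the variance split.** At `S = 100` with
  variance components of 0.017 (correlated) versus 0.038 (heterogeneity),
  the data barely distinguish the smooth from the rough field: the exact
  Gaussian-integral oracle in the test suite shows the marginal posterior
  of `sigma_mu2` concentrating well below the generating value, with
  `sigma_v2` absorbing the sum. The sampler reproduces that posterior
  faithfully (it matches the oracle); the point spatial fraction on
  model-generated data at this size is therefore much smaller than the
  fraction implied by the generating components. This is a property of
  the model at desk scale, not a defect of the chains — and it is why the
  published fractions are reproduced from reported variance components
  rather than re-estimated from synthetic data.
* **Spatial confounding.** Conditional on one realized spatial field,
  credible intervals for covariates that overlap the smooth field are
  mildly narrower than their frequentist scatter (z-score s.d. ≈ 1.1–1.2
  across replicates). Pooled empirical coverage of the 95% intervals
  across 20 replicate fits sits near 92–94%, which the recovery test
  gates at 90%.
* Temporal structure (day-of-week, drift over the study period) is out of
  scope, as are zero-inflated variants, proper-CAR (Leroux) alternatives
  and WAIC/LOO comparison.

## Reproducibility

Every generator and the sampler are deterministic under fixed seeds
(single-threaded; chain `c` of a fit uses `seed + c - 1`). The pipeline
(`run_pipeline()`) derives all stage seeds from one master seed and writes
them to `manifest.json` alongside the configuration hash, so a report
bundle can be reproduced bit for bit.
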