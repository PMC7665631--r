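# speedcount

Bayesian hierarchical spatial count models for vehicle speeding events
extracted from GPS trajectory data.

Road-safety studies increasingly measure speeding not with radar guns or
questionnaires but by mining commercial-fleet GPS traces: every pair of
consecutive fixes yields an average speed that can be compared with the
posted limit of the matched road segment. `speedcount` implements that
pipeline end to end for road-segment-level analysis:

1. **Event extraction** — grid-based map matching of GPS points to road
   centerlines (100 m cells), exclusion of points within 30 m of
   intersections, U-turn/wrong-way anomaly screening, pairwise average
   speeds `v = 3.6 ΔD/ΔT`, classification (*speeding*: `v` strictly above
   the limit; *serious*: strictly above 1.2× the limit), and merging of
   consecutive speeding pairs into complete events.
2. **Count modelling** — per-segment frequencies `Y_s` of total and
   serious events are fitted with four hierarchical models:

   | model | data layer | spatial effects |
   |---|---|---|
   | BHPLM  | `Y_s ~ Poisson(λ_s)` | — |
   | BHNBLM | `Y_s ~ NB(r_s, p_s)`, `p_s = r_s/(λ_s+r_s)` | — |
   | BHSPLM | Poisson | `μ_s + ν_s` |
   | BHSNBLM | negative binomial | `μ_s + ν_s` |

   with `log λ_s = a₀ + Σ_k X_ks β_k (+ μ_s + ν_s)`, where `μ` is an
   intrinsic CAR (ICAR) spatially correlated effect over the segment
   adjacency graph and `ν` is iid normal heterogeneity — the
   Besag–York–Mollié decomposition. Priors: `β_k, a₀ ~ N(0, 10000)`,
   `σ²_μ, σ²_ν ~ InvGamma(0.5, 0.00005)`, `r_s ~ Gamma(5, 0.5)`.
3. **Inference and assessment** — adaptive Metropolis-within-Gibbs
   sampling (Rcpp core) with two chains, Gelman–Rubin diagnostics, trace
   export, 95% credible-interval significance screening with backward
   elimination, DIC model comparison (`DIC = D̄ + p_d`, 5-point
   equivalence rule) and spatial-fraction analysis
   `σ²_μ / (σ²_μ + σ²_ν)`.
4. **Synthetic data with ground truth** — a road-network generator
   (connected planar layout, study-condition covariate marginals, segment
   lengths in 4.386–489.948 m), exact ICAR effect sampling, count
   simulation from all four models, and GPS trajectory simulation with
   planted speeding episodes that downstream extraction must recover
   exactly.

The methods vignette (`vignettes/spatial-speeding-models.Rmd`) documents
the model, the sampler design and the generator's assumptions in detail.

## Worked example

```r
library(speedcount)

network <- generate_road_network(100, seed = 1)
network <- generate_covariates(network, seed = 2)
truth   <- default_truth("total", adjacency = network$adjacency, seed = 3)
y       <- simulate_counts(network, truth, seed = 4)

fit <- fit_model(y, as.matrix(network$covariates),
                 model_spec("poisson", TRUE, 10), network$adjacency,
                 config = mcmc_config(seed = 11))
fit
#> speedcount_fit: BHSPLM - 2 chains x 15000 stored draws, 213 parameters
#>   max PSRF (monitored): 1.0015  coef acceptance: 0.364

summarize_posterior(fit)[c(1, 9, 10, 11), ]
#>          parameter    mean       sd   lower   upper significant
#> 1  speed_limit_ind 2.55518 0.060309 2.43504 2.67345        TRUE
#> 9    work_zone_ind 1.26274 0.068021 1.12783 1.39550        TRUE
#> 10        length_m 0.00701 0.000377 0.00627 0.00776        TRUE
#> 11              a0 4.75780 0.093643 4.56711 4.94050        TRUE

dic(fit)
#> DIC = 1064.183 (D-bar = 967.556, p_d = 96.627)
```

The chains converge (max PSRF 1.0015 < 1.1), the generating coefficients
(speed-limit indicator 2.538, work zone 1.244, length 0.007 per metre,
intercept 4.667) sit inside their 95% intervals, and the effective number
of parameters (~97) reflects the per-segment random effects. The same
session can verify extraction against planted truth:

```r
plan <- plan_episodes(network, n_total = 3, n_serious = 2, seed = 5)
sim  <- simulate_trajectories(network, plan, seed = 6)
ext  <- extract_events(sim$trajectories, network)
identical(ext$counts$y_total, sim$planted$y_total)
#> [1] TRUE
```

`run_pipeline(run_config(...))` chains all stages — simulate or ingest,
extract, fit all four models to both outcomes, compare by DIC — and writes
a report bundle with a reproducibility manifest. A thin command-line
wrapper lives at `inst/scripts/speedcount.R`
(`Rscript speedcount.R run --config run.yaml`).

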