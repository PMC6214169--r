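# hctmc — hierarchical continuous-time Markov chain movement models

`hctmc` is for movement ecologists who want continuous-time inference on
*how* animals move — speed and directional bias as functions of the
landscape, the clock, and the individual — from ordinary GPS collar data.
It implements a two-stage hierarchical continuous-time Markov chain (CTMC)
analysis of telemetry on a raster landscape, of the kind used to study
fine-scale carnivore movement at the wildland–urban interface, together
with an exact simulator so the whole pipeline can be exercised and
validated without any field data.

## The model

Movement is a CTMC on 100-m raster cells: the animal resides in cell *c*
for an Exp(Σₖ λₖ) time and then moves to rook-neighbor *k* with probability
λₖ / Σⱼ λⱼ, where

```
λ_k = exp{ x_k' β },     x_k = (1, motility values, directional values, persistence)
```

Motility drivers (the current cell's covariate values) scale all four exit
rates and so govern speed; directional drivers (−∇c · u_k per cell
crossing) govern where the animal goes, with positive coefficients meaning
movement toward decreasing covariate values (toward a feature, for a
distance layer); directional persistence (u_prev · u_k) captures residual
autocorrelation.

**Stage 1** fits a Bayesian functional movement model (RW2-penalized grid
coefficients, fixed measurement-error sd, inverse-gamma partial sill) to
each track, draws multiple imputations of the continuous path on a
10-minute grid, and discretizes each to a contiguous cell sequence.
**Stage 2** re-expresses the CTMC likelihood as a latent-variable Poisson
regression — four rows per transition, residence time as offset — and fits
hierarchical models by MCMC:

```
z_ij ~ Poisson(λ_ij),    log λ_ij = log τ_ij + x_ij' β_j
β_j  ~ N(μ, σ²_β diag(φ)),   φ_1 = 1,  log φ_p ~ N(0, 0.04)
μ    ~ N(0, σ²_μ I),         σ²_μ = 0.1
```

with the log-likelihood averaged over the fit-set imputations. The H-GAM
variant Kronecker-expands each covariate with a cyclic cubic spline basis
on the 24 h clock, giving diel time-varying coefficients whose curves close
exactly at midnight. Regularization (σ²_β) is selected and models are
compared by the posterior predictive score on held-out imputations (lower
is better), including the four-model sex-split set (GLM/GAM × all/by-sex).
A nocturnal-revisit clustering rule (≥ 2 nocturnal fixes within 200 m
within 6 days) identifies potential kill sites and turns them into
distance covariates.

## Worked example

Simulate four animals with known population-level effects, observe them
with a 3-hour GPS schedule, impute paths, and fit the hierarchical GLM:

```r
library(hctmc)
land  <- make_landscape(n_layers = 1, dims = c(80, 80), smoothness = 5, seed = 11)
roles <- ctmc_roles(motility = "cov1", directional = "cov1", persistence = TRUE)
truth <- draw_population(mu = c(log(0.25), 0.4, 0.4, 0.3), sd = rep(0.2, 4),
                         J = 4, seed = 12)
geom <- land[["cov1"]]
seqs <- list()
for (j in 1:4) {
  p  <- simulate_ctmc_path(land, truth$betas[j, ], c(40, 40), 7 * 24, roles,
                           seed = 100 + j, individual_id = sprintf("cat%02d", j))
  tr <- observe_gps(p, geom, fix_interval_hours = 3, sigma_obs = 25, seed = 200 + j)
  fp <- fit_functional_path(tr, path_priors(sigma_obs = 25), seed = 300 + j)
  for (ip in draw_imputed_paths(fp, M = 6, fit_count = 4, score_count = 2))
    seqs[[length(seqs) + 1]] <- discretize_path(ip, geom)
}
seqs <- do.call(rbind, seqs)
tab  <- build_latent_table(seqs[seqs$label == "fit", ], land, roles)
fit  <- fit_hctmc(tab, model = "glm", priors = hier_priors(sigma2_beta = 1),
                  schedule = mcmc_schedule(2000, 6000, 1000, 5), seed = 42)
summary(fit)
```

```
Hierarchical CTMC movement model (GLM), 1000 posterior draws

Population-level effects (95% credible intervals):
         coef     mean     sd    q2.5   q97.5
1 (Intercept) -0.46788 0.2686 -0.9897 0.04238
2    mot_cov1  0.02570 0.2559 -0.4725 0.51012
3    dir_cov1  0.21538 0.2824 -0.3008 0.77930
4     persist  0.08538 0.2713 -0.4559 0.58627

phi posterior means:
(Intercept)    mot_cov1    dir_cov1     persist 
      1.000       0.960       0.994       0.947 

acceptance: beta blocks 0.22-0.25, phi blocks 0.45-0.45; 0 clipped predictors
```

The rows are the population-mean effects μ: the baseline log movement rate
(cell crossings per hour; shrunk toward zero by the μ prior — see the
methods vignette's limitations), the motility and directional effects of
the landscape layer, and directional persistence. `coef(fit, "individual")`
gives per-animal posterior means, `plot(fit)` a caterpillar plot (or diel
coefficient curves for a GAM via `backtransform_curves()`). At this desk
scale (4 animals, 7-day windows) the intervals are wide; the directional
and persistence means carry the sign of the simulated truth.

`run_pipeline()` drives the whole chain — simulate (or read tracks),
impute, detect kill sites, build designs, select regularization, fit,
score, compare — from a single YAML/list config, writing every intermediate
as CSV / ASCII-grid / JSON plus a machine-readable `summary.json`.
A thin command-line wrapper lives at `inst/scripts/hctmc-pipeline.R`.

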