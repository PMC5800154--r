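# scmspline

Bayesian joint disease mapping for two-group spatio-temporal binomial
panels: a **shared component model (SCM) with cubic B-spline temporal
terms**, together with the descriptive epidemiology around it and a
synthetic-data generator that makes the whole pipeline testable end to end.

The package is aimed at spatial epidemiologists working with survey panels
of a *non-rare* disease observed by group (male/female), region and survey
wave — the motivating design is hypertension measured in seven Chinese
provinces over eight unequally spaced waves (1991–2011).

## The model

Cases per cell are binomial with a logit link,

    Y[j,i,t] ~ Binomial(n[j,i,t], p[j,i,t]),   logit p = alpha_j + eta[j,i,t]

and the linear predictor splits risk into shared and group-specific parts:

    eta[1,i,t] = (b0_i + RS0_i(t)) * delta_t + S_1(t) + b_{1i} + RS1_i(t)
    eta[2,i,t] = (b0_i + RS0_i(t)) / delta_t + S_2(t) + b_{2i} + RS2_i(t) + beta_it

* `b0_i` — shared spatial field (unobserved common risk factors),
  weighted `delta_t` for men and `1/delta_t` for women per wave;
* `S_j(t)`, `RS.(t)` — cubic B-splines over **calendar years** (the waves
  are unequally spaced), clamped basis, intercept removed and columns
  centred so `K = L + 3` for `L` interior knots;
* `beta_it` — per-wave differential map of women vs. men, intrinsic CAR
  prior on the province contiguity graph;
* `exp(eta)` is reported as a relative odds-ratio surface.

Seven numbered variants (knot sets {1997}, {2000}, {1997,2000},
{1997,2004}, {1997,2000,2004}; with/without the random splines) are
compared by DIC. Posterior sampling is adaptive Metropolis-within-Gibbs in
C++ with sum-to-zero constraints maintained at every draw and a conjugate
Wishart step for the MCAR coefficient precision. The methods vignette
(`vignettes/shared-component-splines.Rmd`) documents the priors, the
identifiability constraints (including the shared/specific ridge and the
dedicated proposal that traverses it) and every numerical choice.

## Worked example

```r
library(scmspline)

# descriptives on the packaged 7-province x 8-wave count table
panel <- table2_fixture()
overall <- prevalence(panel, by = "wave")
overall[overall$wave %in% c(1991, 2011), ]
#>   wave cases    n prevalence
#> 1 1991  1270 9013      14.09
#> 8 2011  2622 8101      32.37

adj <- default_adjacency()
pw <- prevalence(panel, by = c("region", "wave"))
vals <- setNames(pw$prevalence[pw$wave == 2011], pw$region[pw$wave == 2011])
morans_i(vals, adj, n_perm = 999, seed = 1)
#> Moran's I = 0.6954, permutation p = 0.0640 (999 permutations)

# fit the final model variant to a synthetic two-gender panel
sim <- simulate_panel(simulation_scenario(seed = 1))
fit <- fit_scm(sim$panel, adj, model_spec(5),
               mcmc_config(n_chains = 2, n_iter = 10000, burn_in = 2500,
                           seed = 1))
fit
#> <scm_fit> variant 5 | 2 chains x 7500 kept draws
#>   Dbar 734.5, pD 6.3, DIC 740.7
#>   max PSRF 1.360 (log_delta[5])

head(delta_trajectory(fit), 3)   # per-wave shared-component weights
#>   year      mean    median     lower    upper
#> 1 1991 0.9784796 0.9644663 0.6931429 1.334577
#> 2 1993 1.0296364 1.0056935 0.7610151 1.456357
#> 3 1997 1.0016727 0.9916371 0.7906407 1.297404
```

The overall prevalence rises from 14.09% (1991) to 32.37% (2011); the
strongly positive Moran's I in 2011 (0.70) says province prevalences
cluster spatially by then; the fitted `delta_t` trajectory summarizes how
strongly the shared spatial field loads on each gender per wave (its
intervals are wide — the weights are weakly identified when the shared
field is small, see the vignette; `analysis/03_fit_model.R` runs the same
fit at 2 × 20,000 iterations, reaching max PSRF 1.02).

The full analysis lives in `analysis/` as numbered drivers:
`01_descriptives.R` (prevalence + Moran's I), `02_simulate.R` (reference
synthetic panel), `03_fit_model.R` (variant-5 fit and posterior surfaces),
`04_model_comparison.R` (DIC table), `05_sensitivity.R` (three precision
hyperpriors). Each writes its tables under `results/`.

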