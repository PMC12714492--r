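# occuhier

Hierarchical (two-scale) Bayesian occupancy modelling for sign surveys,
with a conflict-association toolkit. Written for wildlife ecologists
analyzing large-carnivore distribution: the motivating system is tigers in
and around a protected-area complex, surveyed on a lattice of 10 km x 10 km
grids subdivided into 2 km x 2 km subgrids, with tiger and prey sign
recorded every 100 m of walked trail.

## The model

A grid $i$ is occupied with probability $\psi_i$; within it, subgrid $j$
is *used* by prey ($z^x_{ij}$) and by tigers ($z^y_{ij}$), with tiger use
depending on prey use. All four layers are logistic in standardized
covariates (grid prey abundance, NDVI, log human population density,
elevation):

$$\mathrm{logit}(\psi_i) = b_0 + b_1 \mathrm{Prey}_i + b_2 \mathrm{NDVI}_i
 + b_3 \mathrm{HPD}_i + b_4 \mathrm{Elev}_i$$

$$\mathrm{logit}(\psi^y_{ij}) = \beta^y_0 + \beta^y_1 z^x_{ij} +
  \beta^y_2 \mathrm{NDVI}_{ij} + \beta^y_3 \mathrm{HPD}_{ij} +
  \beta^y_4 \mathrm{Elev}_{ij}$$

Detections are binomial over the $n_{ij}$ surveyed 100-m segments with
per-segment probabilities $\mathrm{logit}(p_{ij}) = d_0 + d_1
\mathrm{NDVI}_{ij} + d_2 \mathrm{Elev}_{ij}$, gated by the latent
indicators ($p^y Z_i z^y_{ij}$ for tigers, $p^x z^x_{ij}$ for prey under
the default gating). Inference is Metropolis-within-Gibbs with data
augmentation under uniform priors; convergence is judged by split-chain
Gelman-Rubin R-hat < 1.1.

Around the model sit the pipeline stages: covariate standardization with
an invertible scaling record, population flooring/log10 transform,
neighbour-mean prey imputation for unvisited grids, a synthetic survey
generator for simulation-based validation, posterior use maps, stratified
2x2 odds-ratio analysis of rescue/conflict records (Woolf and Breslow-Day
homogeneity tests), and harmonic regression for monthly seasonality.

## Worked example

```r
library(occuhier)

# simulate a survey at the study's scale and refit it
des <- sim_design(n_grids = 62, subgrids_per_grid = 25, seed = 5)
sim <- simulate_survey(des)
dat <- impute_prey(sim$data, sim$adjacency)
fit <- occu_fit(dat, occu_control(iterations = 3000, chains = 3,
                                  thin = 5, burn_in = 1000, seed = 16))
fit
#> Two-scale occupancy model fit (Metropolis-within-Gibbs)
#>   chains: 3  retained draws/chain: 400  gating: tiger_gated
#>   max R-hat: 1.0117 (converged)
#>   elapsed: 36.4 s

at_mean_covariates(fit, "grid_occupancy")
#>         quantity      mean    lower     upper
#> 1 grid_occupancy 0.9643456 0.888848 0.9978125
```

The occupancy probability at mean covariates is the inverse-logit of the
grid intercept draws: here the simulated truth was 0.90 and the posterior
interval covers it. `summary(fit)` tabulates all 20
coefficients with 95% credible intervals; `use_map(fit)` returns
per-subgrid posterior use probabilities for mapping or downstream
conflict analysis.

The conflict side works from contingency tables of rescue presence per
subgrid:

```r
ft <- rescue_tables()                      # packaged buffer-zone tables
odds_ratio(ft$overall$prey_use)
#> [1] 3.8125
log_or_test(ft$overall$prey_use, "greater")
#>         Z-test for the log odds ratio
#> data:  13/3/208/183
#> Z = 2.0637, p-value = 0.01952
#> alternative hypothesis: greater
#> sample estimates:
#>     odds ratio log odds ratio             SE
#>      3.8125000      1.3382851      0.6484818

or_homogeneity_test(ft$prey_by_population)
#>         Woolf test of homogeneity of odds ratios
#> data:  2 strata
#> X-squared = 6.1322, df = 1, p-value = 0.01327
#> sample estimates:
#>  OR low_population OR high_population          common OR
#>          0.3448276         10.9841270          3.4929841
```

High prey use nearly quadruples the odds of a rescue in a buffer subgrid,
and the effect differs sharply between high- and low-population strata
(odds ratio 10.98 against 0.34) — the homogeneity test rejects a common
odds ratio.

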