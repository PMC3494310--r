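# sharkbaseline

Hierarchical Bayesian estimation of reef-shark density baselines from
towed-diver surveys.

Reef sharks are nearly absent around populated Pacific islands and
abundant on remote reefs, but remote reefs also sit in different
oceanographic conditions — so the interesting question, *what density
would a populated reef support with no humans around?*, needs a model
that separates human pressure from environment. This package is for
quantitative ecologists working with large-area underwater count
surveys: it fits overdispersed shark counts from towed-diver belt
surveys (>1 ha per tow) to island-level covariates (human population
within 200 km, oceanic primary productivity, minimum sea-surface
temperature, reef area, reef complexity), selects covariates with
latent indicators, checks fit with a posterior-predictive p-value, and
simulates counterfactual human-free baseline densities with credible
intervals and depletion ratios.

## The model

Counts per tow are negative binomial around island mean densities,
which are nested in a positive-truncated normal hyperdistribution whose
location is a linear function of standardized covariates:

    Y_t ~ NegBin(mu_i * a_t, k)                      (tow t, island i)
    mu_i ~ N+( E_i, sigma^2 / n_i )
    E_i  = alpha + sum_j w_j beta_j x_ij

with vague priors N(0,100) on `alpha`, `beta_j`, Gamma(0.01, 0.01) on
the precision 1/sigma^2 and on the overdispersion `k`, and
Bernoulli(0.5) latent indicators `w_j` whose posterior visit
frequencies give model weights. Baselines set the human covariate to
the standardized image of raw zero (through its log(x+1) transform) at
every retained draw. Sampling is an adaptive Metropolis-within-Gibbs
with a compiled (Rcpp) core; details and design rationale are in
`vignettes/shark-baselines-methods.Rmd`.

## Worked example

The original survey records are not public, so the worked analysis runs
on a synthetic survey drawn from the model's own generative process at
the documented study scale (46 islands in 5 regions, 30-40 tows each)
with a known truth: `alpha = 2.5`, standardized effects -1.2 (humans),
0.8 (productivity), 0.5 (minimum SST), `sigma2 = 1`, `k = 1.5`.

```r
library(sharkbaseline)

sim <- simulate_survey(seed = 20260930, area_sst_correlation = -0.66)
cnt <- group_counts(sim$tows, species_group("all_reef_sharks"))

covs <- c("humans_200km", "productivity", "min_sst")
dat <- build_model_data(cnt, sim$design, covariates = covs)
fit <- run_mcmc(dat, model_spec(covs), n_iter = 20000, n_burn = 4000,
                chains = 2, seed = 31)
posterior_summary(fit, c("alpha", paste0("beta.", covs)))
```

```
          parameter     median     lo     hi  rhat
              alpha      2.541  2.406  2.680 1.000
  beta.humans_200km     -1.205 -1.341 -1.082 1.002
  beta.productivity      0.720  0.502  0.938 1.017
       beta.min_sst      0.351  0.178  0.518 1.016
```

Every 95% interval brackets its generating value, and `rhat` near 1
shows the two chains agree. The human effect is strongly negative:
about 1.2 sharks/ha are lost per standard deviation of log human
population. Goodness of fit and the counterfactual:

```r
bayesian_p_value(fit, seed = 32)$bayesian_p
#> 0.571        # ~0.5 indicates a well-fitting model

bt <- baseline_table(fit, cnt, sim$islands,
                     human_covariates = "humans_200km")
head(bt[, c("island_id", "observed_density", "baseline_median",
            "depletion_median_pct")], 2)
#>  island_id observed_density baseline_median depletion_median_pct
#>     MHI_01            0.658            3.66                 18.0
#>     MHI_02            0.858            3.66                 23.4
```

The most heavily populated synthetic islands hold well under a quarter
of their modeled human-free density, and the true baseline lies inside
the reported 95% interval on every island in this run. The full
pipeline — simulate, screen covariates (pairwise correlations, VIF),
select within model sets A/temperature and B/reef-area, diagnose,
predict baselines — is scripted as `analysis/01_simulate.R` through
`analysis/05_baselines.R`, each writing tables under `results/`.

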