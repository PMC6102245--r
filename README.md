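# harvestssm

Bayesian state-space population reconstruction from age-at-harvest data.

Wildlife agencies routinely register every legally harvested animal and age a
tooth from each carcass (cementum annuli), producing long annual tables of
harvest counts by age and sex — often the *only* population data available at
state scale for cryptic, hunted species such as black bears. `harvestssm`
turns such a harvest registry into a statewide abundance estimate with full
posterior uncertainty, requiring no auxiliary survey or telemetry data: the
demographic priors come from a literature review, and the model is designed
to be (and is tested to be) robust to bias in all of them except the
reporting rate.

## The model

Latent pre-season abundance `N[a,s,y]` follows a two-sex, ten-stage
projection (ages 1.5 … 10.5+, terminal class absorbing):

    N[a,s,y]  = N[a-1,s,y-1] * S[a-1,s,y-1]              2 <= a <= 9
    N[A,s,y]  = N[A-1,s,y-1] * S[A-1,s,y-1] + N[A,s,y-1] * S[A,s,y-1]
    N[1,s,y]  = SP_s * CubSa * CubSb * sum_a N[a,F,y-2] * Fec_a

with `Fec_a = LS_a * PR_a` (litter size × pregnancy rate over four fecundity
age groups), cub survival `CubSa`, `CubSb` applied once at recruitment, and a
two-year lag (boundary convention `N[.,F,0] := N[.,F,1]`). Annual survival
factorizes as `S = HS * NS` (harvest-season × non-harvest survival), and the
harvest rate is the latent quantity `HR = (1 - HS) * Rep` with `Rep` the
reporting rate. Harvest-season survival is modelled on a complementary
log-log mortality link with sex-specific long-term means, year random effects
and age-class offsets.

The observation model is two-part: annual registered totals
`O_y ~ Poisson(sum N * HR)` and aged/sexed counts
`C[.,.,y] ~ Multinomial(n_aged, p ∝ N * HR)`, conditioned on the aged subset
size. Inference is adaptive Metropolis-within-Gibbs (compiled core) with
Gelman–Rubin convergence checks; the full-length configuration is 220,000
iterations × 3 chains, burn-in 20,000, thinning 4, and a scaled "desk"
configuration (20,000 × 3) drives the tests and simulation studies.

The prior-bias sensitivity analysis refits the model under ±10% shifts of
each prior's mean (9 parameters, 18 scenarios, plus optional ±50% shifts of
the initial population) and summarizes each scenario by percent relative
change, `PRC = mean_y((N̂_y - N_y)/N_y) × 100`, and the coefficient of
variation, `CV = RMS(N̂ - N)/mean(N) × 100`, against the unbiased fit.

## Worked example

```r
library(harvestssm)

priors <- build_default_priors()          # packaged demographic prior table
fx     <- make_fixture("paper_shape", tempdir(), seed = 1)   # synthetic registry
harvest_summary(fx$data)
#> $mean_O        [1] 4402.75
#> $se_O          [1] 170.6251
#> $range_O       [1] 3764 5064
#> $aged_fraction [1] 0.8598831

fit <- run_mcmc(fx$data, priors, desk_mcmc_config(seed = 7))
max(fit$diagnostics$rhat)
#> [1] 1.043373
subset(posterior_summary(fit), variable %in%
       c("Rep[F]", "NS", "N_total[2009]", "N_total[2017]"))
#>       variable       mean         sd       q2.5      q97.5     rhat
#>         Rep[F]  0.9666020 0.02185661  0.9111126  0.9936804 1.023079
#>             NS  0.9340713 0.01692880  0.8994162  0.9658479 1.036763
#>  N_total[2009] 24948.70   1566.366   22417.44   28470.75   1.039153
#>  N_total[2017] 20465.91   2241.716   16547.76   25444.35   1.013936
```

A mean harvest of ~4,400 with ~86% of kills aged/sexed matches the shape of
the registry the generator emulates. The registry was generated with a true
initial population of 24,200, true reporting rate 0.98 and true non-harvest
survival 0.95 — all inside their 95% credible intervals above, with every
Gelman–Rubin statistic under the 1.1 convergence bar. `run_sensitivity()` produces the 18-row
prior-bias table (with `N/A` rows where a +10% shift would push a probability
mean above 1), `cpue()`/`trend_regression()` compare the abundance trend to
catch-per-unit-effort, and the command-line pipeline

```sh
Rscript inst/cli/harvestssm simulate --fixture paper_shape --out sim
Rscript inst/cli/harvestssm fit --registry sim/paper_shape_registry.csv --out fit
Rscript inst/cli/harvestssm sensitivity --registry sim/paper_shape_registry.csv --out sens
```

chains the stages with per-run manifests. See the methods vignette
(`vignettes/age-at-harvest-ssm.Rmd`) for the modelling assumptions, numerical
choices and limitations.
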