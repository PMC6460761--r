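# coaldrift

Tests whether phenotypic divergence between isolated populations exceeds
what genetic drift can explain, by comparing full posterior
*distributions* of neutral and phenotypic differentiation instead of
point estimates. It is written for population geneticists and
evolutionary ecologists working on island (or otherwise discrete)
population pairs with (i) posterior draws from an
isolation-with-migration coalescent analysis and (ii) per-individual
measurements of quantitative traits.

## The method

**Directional F_ST distributions.** Posterior draws of the effective
number of migrants *Nm* are transformed draw-by-draw under Wright's
island model with Takahata's finite-deme correction,

```
F_ST = 1 / (1 + 4·Nm·d²/(d−1)²),
```

giving a separate F_ST distribution per direction of migration. Since
*Nm* is a compound parameter (θ·m/4 = N_e·M), the transform does not
depend on the mutation rate. Coalescent-scaled parameters also convert
to natural units: N_e = θ/4μ, t = τ/μ, with μ the geometric-mean
multilocus substitution rate and a stated generation time.

**Trait P_ST posteriors.** A Bayesian hierarchical variance-components
model, y = μ + island + sex(+island) + covariates + ε, with half-Cauchy
priors on both standard deviations, fitted by a built-in seeded Gibbs
sampler, yields per-draw

```
P_ST = (c/h²·σ²_B) / (c/h²·σ²_B + 2·σ²_W)
```

at the best case c = h². Convergence diagnostics (Gelman–Rubin PSRF,
effective sample size) and posterior predictive checks are reported.

**The drift test.** The two distributions are compared by the overlap of
their boundary-corrected kernel densities on [0, 1], their 5%/95% tail
quantiles, and the critical ratio
(c/h²)₍crit₎ = (1 − P_ST,0.05)·F_ST,0.95 / (P_ST,0.05·(1 − F_ST,0.95)) —
the smallest additive-contribution ratio at which the trait still
exceeds the neutral expectation. A multi-locus Hedrick G′_ST (haplotypes
as alleles, Nei–Chesser corrections, stratified bootstrap) provides the
traditional symmetric-flow baseline.

## Worked example

Synthetic data with known truth — a migration regime with median
Nm = 0.325 and an 8-standard-deviation trait gap (far beyond drift):

```r
library(coaldrift)

nm  <- genNmDraws(median = 0.325, log_sd = 0.9, n = 10000,
                  seed = 1, population = "islandB")
fst <- fstDistribution(nm, d = 2)
summarizePosterior(fst)
#> PosteriorSummary (n = 10000)
#>   mode 0.0861133; 95% HPD [0.0168868, 0.472321]
#>   quantiles:
#>       2.5%         5%        50%        95%      97.5%
#> 0.03108808 0.04157330 0.16323906 0.46660521 0.54296219

tt  <- genTraits(c(islandA = 0, islandB = 8), sigma_w = 1, seed = 2)
fit <- fitTraitModel(tt, modelSpec("trait"),
                     mcmcConfig(burn_in = 5000, n_iter = 10000,
                                thin = 10, seed = 3))
fit
#> TraitFit: trait 'trait', 2000 draws x 6 parameters, 2 chains
#>   P_ST (c = h^2): median 0.994 (2.5%: 0.806, 97.5%: 1.000)
#>   worst PSRF 1.0010 (sigma_w2); min ESS 1629

driftCompare(fit, fst)
#> DriftComparison: trait vs F_ST[islandB]
#>   overlap 0.01117 (threshold 0.05); P_ST 5% = 0.8663; F_ST 95% = 0.4666
#>   critical c/h^2 = 0.135; verdict: drift_rejected
```

Reading the output: the F_ST distribution implied by the migration
posterior is wide (mode 0.086, 95% HPD up to 0.47), but the P_ST
posterior sits almost entirely above it — the densities overlap by only
1.1%, the P_ST 5% quantile (0.87) clears the F_ST 95% quantile (0.47),
and the comparison stays valid down to c/h² ≈ 0.14. Drift is rejected
as the sole explanation for the trait gap.

Natural-parameter conversion uses the published coalescent scale
directly:

```r
neFromTheta(0.625, perGenerationRate(5.67e-7, 2))   # ~138,000 individuals
splitTimeFromTau(0.703, 5.67e-7) / 1e6              # ~1.24 Ma
```

A shell entry point wraps the same functions
(`inst/scripts/coaldrift`): subcommands `convert`, `pst`, `drift`,
`gst`, `simulate`, all file-in/file-out with JSON manifests.

## Package layout

* `R/convert.R`, `R/posterior.R` — coalescent-parameter conversion, F_ST
  transform, posterior summaries (KDE mode, shortest-interval HPD,
  type-7 quantiles)
* `R/traitmodel.R` — hierarchical trait model, Gibbs sampler, PSRF, ESS,
  posterior predictive checks
* `R/drift.R` — KDE overlap, critical c/h², comparison and report
* `R/gst.R` — infinite-sites filter, Nei–Chesser heterozygosities,
  Hedrick G′_ST, stratified bootstrap
* `R/simulate.R` — synthetic-data generators and the bundled
  drift/selection scenarios
* `R/io.R`, `R/cli.R` — file formats and shell-facing commands
* `vignettes/coaldrift-methods.Rmd` — the model, priors, numerical
  conventions, and what the synthetic calibration does and does not show
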