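---
title: "Testing drift against selection with coalescent-based F_ST and Bayesian P_ST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing drift against selection with coalescent-based F_ST and Bayesian P_ST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldrift)
```

## The question the package answers

Two isolated populations often differ in a quantitative trait — a call
frequency, a body dimension. The null explanation is genetic drift: with
little gene flow, trait means wander apart even without selection. The
classical test compares the trait-differentiation index Q_ST with the
neutral-marker fixation index F_ST; when additive genetic variances are
unavailable (almost always, in wild populations), the phenotypic analogue
P_ST stands in for Q_ST. `coaldrift` implements a fully distributional
version of this comparison for a two-island (or d-island) system:

1. **F_ST from migration posteriors.** Posterior draws of the effective
   number of migrants Nm — typically from an isolation-with-migration
   coalescent analysis, whose retained draws the package consumes as a
   plain table — are pushed through Wright's island-model relationship
   with Takahata's finite-deme correction,

   F_ST = 1 / (1 + 4·Nm·d²/(d−1)²),

   draw by draw. This propagates the full posterior uncertainty of the
   migration estimate into an F_ST distribution, separately for each
   direction of migration, without assuming any parametric form. Because
   Nm is a compound parameter (θ·m/4 = N_e·M when θ = 4N_eμ and m = M/μ),
   the transform is free of the notoriously uncertain mutation rate.

2. **P_ST from a hierarchical Bayesian trait model.** Per-individual
   trait values are modeled as

   y_ij = μ + a_j + s_[j],sex(i) + Σ β_k x_ik + ε_ij,

   with island effects a_j ~ N(0, σ²_B), residuals ε ~ N(0, σ²_W),
   half-Cauchy priors on both standard deviations and diffuse normal
   (sd 1000) priors on the mean, sex effects and covariate slopes. Each
   retained draw yields

   P_ST = (c/h²·σ²_B) / (c/h²·σ²_B + 2σ²_W),

   evaluated at c = h² (the best-case assumption that the proportion c of
   between-population variance that is additive equals the heritability);
   other ratios can be recomputed from the stored variance draws with
   `pstFromVariances()`.

3. **The comparison.** The two distributions live on [0, 1] and are
   compared by (i) the overlap of their boundary-corrected kernel
   densities, (ii) their 5%/95% tail quantiles, and (iii) the critical
   ratio

   (c/h²)_crit = (1 − P_ST,0.05)·F_ST,0.95 / (P_ST,0.05·(1 − F_ST,0.95)),

   the smallest c/h² at which the trait's lower tail still clears the
   neutral upper tail. Drift is reported as rejected when the overlap
   falls below a threshold (default 0.05) *and* the tails do not cross;
   both ingredients are always printed, the verdict is a convention.
   Overlaps are always reported as proportions, never percentages.

A sequence-based baseline is included: Hedrick's standardized G'_ST from
multi-locus haplotype alignments (whole haplotypes as alleles,
Nei–Chesser small-sample corrections, harmonic-mean sample size), with an
infinite-sites site filter and a bootstrap interval stratified by
population. It represents the traditional equilibrium, symmetric-flow
estimate the directional F_ST distributions improve upon.

## A worked run

```{r pipeline, eval = FALSE}
nm  <- genNmDraws(median = 0.325, log_sd = 0.9, n = 10000,
                  seed = 1, population = "islandB")
fst <- fstDistribution(nm, d = 2)
tt  <- genTraits(c(islandA = 0, islandB = 8), sigma_w = 1, seed = 2)
fit <- fitTraitModel(tt, modelSpec("trait"), mcmcConfig(seed = 3))
driftCompare(fit, fst)
```

## Numerical conventions

Choices that affect reproducibility are fixed and documented rather than
left to defaults of the moment:

* **Quantiles** everywhere use linear interpolation of order statistics
  (type 7), so tail quantiles of F_ST and P_ST are bit-reproducible.
* **Posterior modes** are the argmax of a Gaussian kernel density with
  Silverman's bandwidth on a 512-point grid spanning the draw range.
  Published point estimates from coalescent software are joint-density
  modes under that software's own smoothing; the product of marginal
  modes of θ and m is *not* the mode of the Nm draws, and the package
  documents its own convention instead of guessing another tool's.
* **HPD intervals** are shortest windows of ⌈mass·n⌉ consecutive order
  statistics.
* **KDE overlap** uses Gaussian kernels with Silverman bandwidth,
  boundary-corrected by reflection at 0 and 1 (differentiation indices
  live on [0, 1]; without reflection, mass piles up near F_ST ≈ 0 and
  P_ST ≈ 1 and leaks off-support), evaluated on a shared 512-point
  uniform grid and integrated by composite Simpson's rule. Each reflected
  KDE integrates to 1 within 0.01 on this grid.
* **Human-readable rounding** follows field convention — effective sizes
  to the nearest thousand, split times to two decimals in Ma — while raw
  values are always retained in machine output.
* Degenerate inputs are handled explicitly: constant draws give
  zero-width HPDs; monomorphic loci are excluded from G'_ST pooling with
  a notice; a P_ST 5% quantile of 0 (or F_ST 95% of 1) flags an infinite
  critical ratio rather than dividing by zero.

## The sampler, and why it is trusted

The trait model is fitted by a purpose-built component-wise Gibbs
sampler, deterministic given the seed, with no external MCMC engine. All
location parameters are conjugate. The half-Cauchy priors are handled
*exactly* through their inverse-gamma scale-mixture representation
(σ² | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/A²)), which makes both variances
conjugate too. Two additions matter in practice:

* a **group-translation ("sweep") Gibbs move** that shifts mass between
  the grand mean and the island effects; with only two islands the two
  are additively confounded and plain Gibbs stalls, while the sweep move
  restores near-iid mixing of μ and a_j;
* in the correlated model — island-specific (intercept, male-effect)
  pairs with a jointly bivariate normal prior, uniform(−1, 1) prior on
  the correlation — the covariance block is updated by univariate
  random-walk Metropolis on (log σ_B, log σ_S, atanh ρ) with fixed step
  sizes (0.5, 0.5, 0.8).

Correctness is checked against an independent 1-D quadrature of the
σ²_B posterior (island effects and grand mean marginalized analytically):
long chains reproduce exact tail probabilities to Monte-Carlo error. The
test suite also verifies the Gelman–Rubin PSRF and the paired
initial-positive-sequence effective sample size against independently
coded textbook formulas, and runs posterior predictive checks (per
population-by-sex mean and sd, posterior predictive p-value
P(T_rep ≥ T_obs)).

Default chain lengths mirror common practice for this model class:
burn-in 25,000, 25,000 sampling iterations thinned every 25, at least two
chains, targeting effective sizes above 1,600 (reported, not enforced).
Tests and calibration loops use shorter, explicitly configured runs —
typically 500–5,000 burn-in with 1,000–50,000 sampling iterations —
chosen per check so that Monte-Carlo error is small relative to the
tolerance being asserted.

## Priors, and an honest caveat about two groups

"Weakly informative" is relative to the data scale. The half-Cauchy scale
defaults to 100 on the standard-deviation scale (prior variance of at
least 10,000 on the variance scale — the only coherent reading of that
phrase, since a half-Cauchy has no finite variance). With only two
populations, σ²_B is estimated from two island effects and its posterior
is strongly prior-sensitive: exact quadrature shows that under a null
simulation (no true island difference, σ_W = 1, 200 individuals per
island) the P_ST posterior still places roughly half its mass above 0.5,
because the prior admits σ_B up to ~100 almost uniformly. Consequently:

* P_ST posteriors from two-island designs are *wide*; that width is real
  information, and the drift test consumes the whole distribution rather
  than a point estimate.
* P_ST is exactly invariant under affine rescaling of the trait only
  when `prior_scale_sd` is rescaled with it. At the default scale,
  traits measured in units where σ_W is within a couple of orders of
  magnitude of 1–100 (kHz, mm, g) are in the regime the default was
  chosen for. Traits are modeled in raw units; no standardization is
  applied by default.
* Covariates are centered at their sample mean before fitting, so the
  grand mean stays interpretable and the slope priors act on a sensible
  scale.
* Records of unknown sex are excluded whenever a sex effect is in the
  model and retained otherwise; records missing the trait or a modeled
  covariate are always excluded, with a message.

## What the synthetic data do and do not show

The generators produce exactly the three input kinds the pipeline reads,
with known ground truth: lognormal Nm draws (median 0.325 and log-sd
0.9 by default, matching a realistically low and uncertain inter-island
exchange — the log-sd is set so the central 95% of draws spans roughly a
30-fold range); two-island trait tables (island means, per-island male
effects, Gaussian residuals; 15 individuals per island and sex by
default, a realistic field-study scale); and multinomial haplotype
samples realized as biallelic alignments that pass the infinite-sites
filter by construction, with optional gap/ambiguity injection to
exercise the missing-data rules.

Two bundled scenarios fix the end-to-end calibration conditions. Both
share the migration regime above. The *drift* scenario sets the island
gap to 2σ_B with σ²_B = 2σ²_W·F/(1−F) at the median F_ST — a trait gap
of the size drift at that migration level actually produces — and should
not reject drift. The *selection* scenario sets the gap to 8
within-population standard deviations and should reject it. Across
seeded repetitions both verdicts are recovered in ≥ 90% of runs.

What passing these checks does **not** show: the generators draw iid
Gaussian traits and iid haplotypes from fixed frequencies. Real data add
measurement error, within-island structure, linked loci, recombination
(no four-gamete filtering is provided) and non-lognormal migration
posteriors. The pipeline's contract deliberately starts at "posterior
draws of Nm" — the coalescent MCMC itself is out of scope — so the
quality of the F_ST distribution is inherited from whatever produced
those draws.

## Other design decisions

* **G'_ST estimators.** Haplotypes are the alleles (SNP-wise mode is not
  provided); H_S and H_T use the Nei–Chesser small-sample corrections
  with harmonic-mean sample size, and for haploid sequence data the
  observed-heterozygosity term is zero. Multi-locus pooling averages H_S
  and H_T arithmetically across informative loci and then standardizes —
  pooling before standardizing is stated in the output rather than left
  ambiguous. The bootstrap resamples individuals within populations
  (preserving the per-population sizes the estimators correct for), 1000
  replicates by default, percentile 95% interval.
* **Eq.-4 tails.** The critical ratio uses 5%/95% *quantiles*, exactly
  as its definition states, even though summary tables in this
  literature often print 2.5%/97.5% HPD bounds; the two do not coincide
  and the package does not mix them.
* **Verdict threshold.** Overlap < 0.05 plus non-crossing tails. Both
  numbers are always reported so a reader can apply any other
  convention.
* **Draw pairing.** Nm = θ·m/4 requires same-iteration draws; tables of
  unequal length are rejected, never recycled, because θ and m are
  correlated in the joint posterior.
* **File formats.** TSV for draw tables, CSV for trait tables, FASTA per
  locus, JSON for every report and manifest; delimiters are
  auto-detected on read only. Every command writes a manifest echoing
  parameters and package version, making runs idempotent and auditable.

## Known limitations

* Two-group σ²_B is weakly identified by design; the package reports the
  honest wide posterior rather than shrinking it.
* The G'_ST bootstrap interval reflects resampling of individuals only;
  locus-level resampling variance is not added.
* The infinite-sites filter drops sequences left with gaps or Ns after
  filtering (haplotype identity is undefined with missing data), which
  can shrink sample sizes at gappy loci.
* P_ST ≈ Q_ST only as far as the c/h² assumption carries; the critical
  ratio quantifies, but cannot remove, that dependence.
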