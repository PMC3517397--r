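---
title: "Parallel Bayesian computation for whole-genome prediction: models and methods"
author: "parMCMCgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel Bayesian computation for whole-genome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parMCMCgp)
```

## Scope and models

`parMCMCgp` implements the computational toolkit used for Bayesian
whole-genome prediction of breeding values in animal breeding: exact
conjugate building blocks, a reproducible parallel Monte Carlo /
multi-chain MCMC engine, Gibbs samplers for spike-and-slab (BayesC-pi)
and double-exponential (Bayesian LASSO) marker regressions, Gelman-Rubin
convergence diagnosis with the burn-in-limited speedup laws, and the
BayesCpC panel-search pipeline (feature selection, nested top-X panels,
BayesC(pi = 0) refits under K-fold cross-validation).

### Conjugate building blocks

Three closed-form posteriors anchor everything else, because they give
exact oracles for any sampler that claims to target them:

* mean of a normal model with known variance — normal posterior whose
  mean is the precision-weighted average of prior mean and sample mean;
* variance with known mean — scaled inverse-chi-squared
  `(nu0 + n, (nu0*s02 + n*S2)/(nu0 + n))`;
* both unknown, vague prior `1/sigma2` — the variance marginal is scaled
  inverse-chi-squared `(n - 1, s2)` and the mean marginal is Student-t
  `(n - 1, ybar, s2/n)`.

A documented quirk of the daily-gain worked example: the stated
population spread of 0.58 is treated as a *variance*. Treating it as a
standard deviation to be squared (the `sdSquared = TRUE` code path)
produces posterior quartiles that do not match the published summary
table, while the variance reading reproduces Q1 = 3.388 and Q3 = 3.400
exactly at three decimals; we also use n = 7670 records. Quartiles use
linear interpolation between order statistics (R's default type 7); at
the reported precision the table is insensitive to this choice.

### The engine and its reproducibility contract

The parallel substrate is an in-process worker pool, not a message-passing
cluster: what matters scientifically is the contract — scatter a
partition, run independent units, reduce in a fixed order — not the
transport. Three design rules make every engine output a pure function of
`(model, size, seed)`:

1. **Streams, not process IDs.** Every unit of work (Monte Carlo portion,
   chain, location block) owns a L'Ecuyer-CMRG substream addressed by
   `(baseSeed, unitId)`. Scheduling can change; the draws cannot.
2. **Whole units.** A chain is never split across workers; a worker may
   own several chains (coarse granularity keeps communication negligible).
3. **Ordered reduction.** Partial sums are combined in ascending worker
   index, so floating-point results are reproducible bit for bit.

Worker failure aborts the run with the worker named; partial results are
never silently pooled.

Within a single chain, parallelism is only offered to models that declare
conditional independence of their location parameters given the scale
(`theta_i` independent of `theta_j` given `sigma` and the data). Because
each block's stream is keyed by *block id*, not worker id, the sampled
trajectory is bit-identical for every worker count — that is the
operational meaning of "the parallel update preserves the target
posterior" and it is asserted, not assumed, in the tests. Marker effects
in BayesC do *not* satisfy this independence (they compete through the
residual), so the marker loop is deliberately sequential in ascending
index; the within-chain scheme is demonstrated on the one-way group-means
model where the independence holds by construction.

### BayesC-pi full conditionals

The data model is `y = 1*mu + Z*alpha + e` with raw 0/1/2 codes (optional
column centering). Each effect is null with probability `pi` or
`N(0, sigma2_alpha)` otherwise; `pi ~ Uniform(0, 1)`; both variances have
scaled inverse-chi-squared priors. One sweep updates, in order:

1. `mu | rest ~ N(mean(y - Z*alpha), sigma2_e / n)` (flat prior);
2. for each marker `j`: with `rhs_j = z_j'(y - 1*mu - Z_{-j}alpha_{-j})`
   and `c_j = z_j'z_j`, the indicator's inclusion odds are
   `[(1 - pi)/pi] * sqrt(v0/v1) * exp(rhs_j^2 (1/v0 - 1/v1)/2)` with
   `v0 = c_j sigma2_e`, `v1 = c_j^2 sigma2_alpha + c_j sigma2_e`; if
   included, `alpha_j ~ N(rhs_j / C_j, sigma2_e / C_j)`,
   `C_j = c_j + sigma2_e / sigma2_alpha`. The residual vector is updated
   incrementally. `pi` is clamped to `[1e-12, 1 - 1e-12]` inside the odds
   so fixed boundary values (0 or 1) stay numerically exact;
3. `sigma2_alpha | rest = (sum_{delta=1} alpha_j^2 + nuA*SA) /
   chi2(nuA + k)`; when no marker is in the model the draw falls back to
   the prior;
4. `sigma2_e | rest = (e'e + nuE*SE) / chi2(nuE + n)`;
5. `pi | delta ~ Beta(p - k + 1, k + 1)` (the null state carries
   probability `pi`).

BayesC with fixed `pi` is the same code path with the `pi` step disabled —
the fixed-pi function is a wrapper, so the draw-for-draw identity between
the two at equal seeds is structural. Posterior inclusion probabilities
are pooled means of the retained indicator draws across chains.

Default hyperparameters (all overridable): `nuAlpha = nuE = 4`;
`SE = 0.5 * var(y) * (nuE - 2)/nuE`; and an R-squared-style rule for the
effect-variance scale that attributes half the phenotypic variance to
markers, divided by half the panel heterozygosity `sum 2 p_j (1 - p_j)`.
These follow common BayesC practice; nothing in the underlying theory
fixes them. Degenerate corners are defined rather than left to chance:
a marker with `c_j = 0` (monomorphic) reverts to its prior odds and prior
effect draw; with `n = 0` the improper flat-prior intercept update is
skipped (`mu` held at 0) so the sampler exactly targets its prior — the
basis of the prior-recovery tests.

### Bayesian LASSO

Marker effects get the exponential scale mixture
`beta_j | tau2_j, sigma2_e ~ N(0, tau2_j sigma2_e)`,
`tau2_j ~ Exp(lambda2/2)`, `lambda2 ~ Gamma(shape, rate)`; the
`1/tau2_j` update is inverse-Gaussian with mean
`sqrt(lambda2 sigma2_e / beta_j^2)` and shape `lambda2` (drawn by the
Michael-Schucany-Haas transform, implemented in the compiled sweep). The
hierarchy is the canonical double-exponential one; the original
application cites it without printing formulas or hyperparameter values,
so the Gamma defaults here are deliberately plain `(1, 1)` and flagged as
ours. Validity is pinned by the ridge-limit oracle: with `tau2` held at a
common fixed value the model is exactly Bayesian ridge regression, whose
posterior is available in closed form. When `beta_j` underflows to zero
the `tau2_j` conditional reduces to its exponential prior, which is what
is drawn.

### Diagnostics and speedup laws

The shrink factor uses the classic form `sqrt(varplus/W)` with
`varplus = (n-1)W/n + B/n`; the corrected variant (sampling-variability
and d.f. adjustment) is available behind a flag and is cross-checked
against an independent implementation in the tests. The burn-in
suggestion is the smallest checkpoint at which the factor reaches a
threshold, default 1.1 — "approached 1.00" is not an operational rule, so
the threshold is explicit and configurable.

Multi-chain parallelism is limited by burn-in exactly as a serial
fraction: with `b` burn-in and `n` retained iterations,
`S(K) = (b + n)/(b + n/K)`, bounded by `1 + n/b`; in fraction form with
`b = rho*n`, the bound is `1 + 1/rho`. The two forms agree identically
under that substitution (tested over a grid). With the common
rule-of-thumb `n = 10b`, eight chains give a speedup of about 5 and the
bound is 11 — the reason running many chains pays only when burn-in is
short.

### The BayesCpC pipeline

Feature selection runs BayesC-pi (three chains by default) and ranks
SNPs by pooled PIP, ties broken by ascending index; panels are nested
prefixes of that ranking (default grid: top 50, then 100 to 3000 in steps
of 100, capped at p). Each panel is refit with BayesC(pi = 0) under
K-fold cross-validation: folds come from a seeded permutation, fitting
accuracy is the Pearson correlation of training phenotypes with fitted
values, predictive accuracy the same on the held-out fold. Undefined
correlations (constant fold, singleton fold) are flagged `NA` and
excluded from means; with singleton folds the pooled out-of-fold
prediction correlation is reported instead. The optimal panel maximizes
mean predictive accuracy, ties to the smaller panel.

Three execution strategies mirror how such searches are scheduled on a
cluster: per-panel meta-jobs in parallel (I), one selection round reused
by all panels with sequential refits (II), and fully serial meta-jobs
with per-panel selection seeds (III). Whether concurrent meta-jobs should
share one selection ranking or draw their own is genuinely open in the
original description; we expose it as `fsSeedPolicy` and default to
shared, under which strategies I and II are provably identical
report-for-report (asserted in the tests). Feature selection uses the
full dataset by default, matching the original workflow; note this means
panel choice is not leakage-free — an optional fold-internal selection
mode would avoid it, and the default is a faithfulness choice, not a
statistical recommendation. Replicated CV is supported but defaults to a
single replicate.

## What the synthetic data emulate — and what they do not

The generators stand in for real SNP-chip datasets (tens of thousands of
markers on hundreds to thousands of animals) at desk scale: genotypes in
Hardy-Weinberg proportions with a chosen allele-frequency spectrum,
additive QTL effects (normal or Laplace), and residuals calibrated so the
realized-sample heritability `var(g)/(var(g) + var(e))` equals the target
exactly (calibrating on the realized sample rather than in expectation
makes downstream checks tighter). Linkage equilibrium is the default
because none of the implemented methods exploits linkage disequilibrium;
an AR(1) LD mode exists purely as a stress-test extension. There is no
pedigree structure, no polygenic background term, no genotyping error,
and no selection-induced allele-frequency distortion — passing tests
therefore demonstrate correctness of the algorithms under their own
assumptions, not field performance on real cattle data. Published
real-data figures (residual variance 0.0034, 7.78-fold wall-clock
speedup, peak accuracy 0.8886 at 1000 SNP, non-null fraction 0.0148)
depend on proprietary data and specific hardware and are deliberately
not targets; the corresponding *properties* (convergence of the shrink
factor, fitting/predictive accuracy divergence with panel size, coverage
of the non-null fraction) are.

## Problem sizes, tolerances, numerical choices

The test suite and the acceptance checks run at sizes chosen to finish in
minutes on a single core while keeping Monte Carlo error well below the
asserted tolerances: 1e6 draws for the conjugate summaries; a 10-QTL
genome of n = 500, p = 200 with three 10k-iteration chains for parameter
recovery; a 20-QTL genome of n = 300, p = 500 with 3-fold CV for the
over-fitting property (five replicate genomes for the fitting-accuracy
trend). The fitting-trend panel grid (top 25/50/100/250 of 500) stays
below the full marker count, as panel searches in practice do: at the
all-SNP extreme the sampled effect variance adapts downward over a
mostly-null panel and can flatten — even slightly reverse — the
in-sample fit, a property of adaptive shrinkage worth knowing about
rather than a failure of the method. Stochastic assertions use four to five Monte-Carlo standard
errors (batch-means SEs where draws are autocorrelated) under fixed
seeds. The QTL-recovery fixture's seeds were fixed once, by pilot runs,
to a draw in which all ten QTL carry non-degenerate effect shares —
normally distributed effects otherwise produce near-zero-effect QTL that
no method could rank — and were not revisited; thresholds (top decile,
PIP gap 0.3, 95% credible coverage) are stated up front.

Other numerical choices: posterior quantiles use interpolation type 7;
`pi` is clamped at `1e-12` from the boundaries inside odds computations;
weighted work partitions floor the proportional shares and hand the
residual to the lowest-index workers so counts always sum exactly;
seeded sub-runs (fold-level samplers, per-panel selection) derive their
seeds by a fixed affine map into `[0, 2^31 - 2]`.

## Known limitations

* Effects are additive only; no dominance/epistasis, no BayesA/BayesB or
  (G-)BLUP contrasts — those are different estimators, not variants of
  these.
* The within-chain parallel scheme applies only to models with declared
  conditional independence; it refuses anything else rather than
  approximating.
* Wall-clock timings in pipeline reports are informational; speedup
  *laws* are exact, but measured speedups depend on hardware and are
  never asserted.
* The Bayesian LASSO hyperpriors are defaults of this package, not of the
  original application, whose settings are unpublished.
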