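---
title: "Calling zero inflation in single-cell UMI counts by Bayesian model selection"
author: "zicall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling zero inflation in single-cell UMI counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zicall)
```

## The problem

Droplet-based single-cell RNA-seq produces UMI count matrices dominated by
zeros. Whether those zeros require *zero-inflated* count distributions —
an extra point mass of "obligate" zeros on top of Poisson or negative
binomial sampling — is a long-running controversy: zero-inflated models
are popular, while studies of technical controls argue plain P/NB models
suffice. `zicall` frames the question as a per-gene model choice among
four generalized linear models and answers it with out-of-sample
predictive accuracy rather than goodness-of-fit.

## Model

For gene $g$ with counts $y_c$ over cells $c = 1,\dots,C$, all four
families share a log-link mean with a fixed sequencing-depth offset:

$$\log \mathbb{E}[y_c] = \log(T_c / 10^4) + \beta_{\text{group}(c)},$$

where $T_c$ is the cell's total UMI count. The offset coefficient is fixed
at 1 (estimating it is known to overfit), so $\mu = e^\beta$ is directly a
rate of expression in UMI per 10,000 total UMI. Groups are cell-means
coded: one log-rate per covariate level (cell type, sex), no global
intercept. The divisor $10^4$ is exposed as `offset_divisor`.

The four families are:

* **P**: Poisson.
* **NB**: negative binomial, mean–shape parameterization with
  $\mathrm{Var} = \mu + \mu^2/r$. Large shape $r$ approaches Poisson;
  $1/r$ is the overdispersion.
* **ZIP / ZINB**: each observation is an obligate zero with probability
  $\pi_0$, otherwise a P/NB draw. The zero component is an intercept-only
  logistic — $\pi_0$ is constant across cells, so cell types differ in
  their zeros only through their rates.

They form a nesting partial order (P below NB and ZIP; NB and ZIP below
ZINB; NB and ZIP not nested in each other) which drives selection.

## Priors and fitting

The reference publications for this procedure do not state priors, so the
defaults here are the package's own weakly informative choices
(`prior_spec()`): $\beta \sim N(0, 5^2)$, $1/r \sim \mathrm{Exp}(1)$,
$\operatorname{logit} \pi_0 \sim N(0, 1.5^2)$. They are proper and keep
all-zero or near-zero genes finite and stable; an all-zero gene under a
zero-inflated family is additionally flagged non-identifiable
(`converged = FALSE`) because $\pi_0$ and $\mu$ trade off freely there.

`fit_gene()` has two modes:

* **`approx`** (default): posterior mode by BFGS, curvature by finite
  differences, then draws from a multivariate Student-$t$ (7 df) centered
  at the mode with the Laplace covariance. Each draw carries the exact
  correction $\log p(\theta \mid y) - \log q(\theta)$, so downstream
  importance-sampling computations target the true posterior, not the
  approximation. The heavier-than-Gaussian proposal tails keep those
  ratios bounded for the skewed $\pi_0$ posteriors.
* **`mcmc`**: adaptive random-walk Metropolis (2 chains x 1,000 post-warmup
  draws by default), initialized at the Laplace mode with the Laplace
  proposal covariance and Robbins–Monro scale adaptation toward 30%
  acceptance during warmup. Convergence requires split-chain
  $\widehat{R} < 1.05$ for every parameter.

Non-convergence never raises: genes stay visible in all outputs with a
flag, mirroring how a real analysis keeps a non-convergent gene in its
tables.

Cells sharing the same (count, depth, group) triple contribute identical
likelihood terms, so all per-cell computations are collapsed to unique
triples internally. At constant simulated depth this reduces thousands of
cells to a few dozen evaluation points.

## Model selection by LOO ELPD

Predictive accuracy is the leave-one-out expected log predictive density

$$\mathrm{ELPD} = \sum_{c=1}^{C} \log p(y_c \mid y_{-c}),$$

estimated by Pareto-smoothed importance sampling over posterior draws
(`elpd_loo()`): raw per-cell ratios are smoothed by a generalized Pareto
fit to the weight tail (empirical-Bayes grid estimator; tail size
$\min(0.2S, 3\sqrt{S})$). The fitted tail shape is the standard
reliability score: cells above 0.7 are recomputed exactly by refitting
without the cell. For models with at most 4 parameters the refit
predictive density is a deterministic ratio of marginal likelihoods
integrated by adaptive Gauss–Hermite quadrature; larger (covariate)
models average the predictive density over refit draws. A brute-force
oracle (`elpd_loo_exact()`, one refit per cell) exists for validation and
agrees with the importance-sampling estimate within 0.1 total ELPD on
small fixtures.

The SE of an ELPD difference is $\sqrt{C}$ times the standard deviation
of the paired per-cell differences, computed on the expanded per-cell
vectors.

`select_family()` applies a deterministic demotion ladder: start at the
ELPD-maximizing family; repeatedly demote to the least-complex strictly
simpler family whose deficit is within $k$ SEs of the pairwise
difference; NB/ZIP ties go to the higher ELPD, then NB. One deliberate
extension beyond strict nesting: a ZIP call must also hold its $k$-SE
margin against NB, the preferred reference model at equal complexity.
Without this rule, a non-inflated gene whose ZIP ELPD marginally exceeds
NB's (routine model mimicry at low expression — confirmed against
quadrature-exact LOO, so not an approximation artifact) starts the ladder
at ZIP and can only ever be compared against Poisson, leaving an
irreducible ~1% false-positive floor at every threshold. With the rule,
the null false-positive rate measured by the calibration study stays
below 0.05 at 1 SE and below 0.01 at 2 SE, the intended calibration
pattern. The threshold $k$ is a reporting device: 0–3 SE span liberal to
conservative calling, with 1 SE the usual operating point and 2–3 SE
appropriate for proving existence of zero inflation.

A note on the overdispersion direction: accounting for cell type removes
type-driven variance from the residual, so the fitted *shape* $r$ rises
and the *overdispersion* $1/r$ falls. Statements that a covariate
"reduces overdispersion" refer to $1/r$; the tests assert that direction.

`information_criteria()` provides the light frequentist complement
(AIC/BIC from penalty-free maximum likelihood); BIC selects the simple
model at least as often as AIC, bracketing the LOO-based choice.

## The synthetic generator

All development and testing uses `gen_heartlike()`, which emulates a
heterogeneous-tissue droplet experiment: per-cell depths from a
log-normal truncated to 746–17,302 with location solved so the mean is
3,819 UMIs/cell (log-scale spread 0.6); per-gene base rates truncated to
0.23–97.4 with mean 1.51 UMI/10K (spread 1.0); 12 cell types with
unequal proportions and per-gene type deviations of the log rate
(`type_effect_sd = 1`, mean-centered); NB shapes $r$ log-normal with
median 1; truth families mixed P : NB : ZIP : ZINB =
2112 : 3183 : 81 : 139 (the classification proportions of a 5,515-gene
heart dataset at 1 SE); $\pi_0$ for ZI genes uniform on [0.1, 0.9]; and
optionally a female-only gene expressed in half the cells. Depth and rate
bounds, the mean depth and rate, the number of cell types and the family
mix are data-anchored; the log-scale spreads, type-effect size and
dispersion law are the package's own choices of a realistic regime.

What the generator does *not* emulate: gene–gene correlation, ambient
RNA, batch effects, continuous cell states, or depth-dependent capture
efficiency. Passing tests therefore demonstrate correctness of the
machinery and calibration under the stated generative model, not
robustness to every artifact of real data.

Companion generators cover the benchmark designs: `sim_null_genes()`
(P/NB truth only, constant depth — any ZI call is a false positive),
`sim_fixed_pi0()` (ZINB truth over a $\pi_0$ grid at constant depth
10,000 or 50,000 UMIs/cell), `sim_from_calls()` (re-simulate each gene
from its called family and fitted parameters, using posterior means), and
`downsample_cells()`.

## Problem sizes and numerical choices

The test and acceptance studies run at desk scale, chosen so each study
completes in minutes while keeping Monte-Carlo error far from the margins
being asserted: 200 genes x 2,000 cells for null calibration, 12
ZINB genes x 3 $\pi_0$ levels x 2 depths x 3 seeds for power, 10 fixtures
of 40–100 cells for the exact-LOO oracle, 50 replicates per family for
parameter recovery. Power comparisons between thresholds and depths are
run in a strongly overdispersed regime (shape drawn around 0.3) because
at shape near 2 and rates above 20 UMI/10K detection saturates at 100%
for 2,000 cells and orderings become unobservable.

Other numerical choices: log-sum-exp for the ZI mixture at zero;
importance weights max-normalized before smoothing; the Pareto shape
estimate carries the standard weak prior pull toward 0.5 for small tails;
non-positive-definite curvature falls back to a ridged inverse and flags
the fit; optimization starts from method-of-moments estimates; ties in
the ladder resolve toward the simpler family. Seeds control every random
step; per-gene fit seeds are derived deterministically from the base
seed, and `fit_gene()` restores the caller's RNG state so interleaved
simulation loops stay independent.

## Limitations

* $\pi_0$ point estimates are not evidence: ZINB fits on NB-truth data
  routinely report $\widehat{\pi}_0$ of 0.2–0.5. Use the model-selection
  call, not $\widehat{\pi}_0$, to claim zero inflation (and the
  cross-fit tooling `crossfit_nb_zinb()` to see the instability).
* The `approx` mode trades a small amount of ELPD accuracy for a large
  speedup; the importance-weight correction removes most of the bias, but
  MCMC mode remains the reference.
* The zero component is covariate-free by design; genes whose extra-zero
  probability varies across cells violate the model.
* Selection calls should not be used to pick per-gene models for
  downstream analysis; the NB GLM with offset and known covariates is the
  recommended robust default.
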