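# zicall

Bayesian count-model selection for zero inflation in single-cell RNA-seq
UMI data.

## What it does, and for whom

Droplet scRNA-seq count matrices are mostly zeros, and whether those zeros
need *zero-inflated* models — an extra point mass of obligate zeros on top
of Poisson (P) or negative binomial (NB) sampling — is a recurring
modeling question. `zicall` answers it per gene, for analysts who want
evidence rather than convention: it fits four generalized linear models
(P, NB, ZIP, ZINB) to each gene's counts and selects among them by
out-of-sample predictive accuracy.

All four models share a log-link mean with a fixed sequencing-depth
offset,

    log E[y_c] = log(T_c / 1e4) + beta_group(c),

so `exp(beta)` is a rate in UMI per 10,000 total UMI; categorical
covariates (cell type, sex) give one rate per level. The NB uses the
mean–shape parameterization, Var = mu + mu^2/r. Zero-inflated variants add
a cell-constant obligate-zero probability `pi0` through an intercept-only
logistic component. Fits are Bayesian (weakly informative priors; fast
Laplace/Student-t approximation or adaptive-Metropolis MCMC).

Models are ranked by the leave-one-out expected log predictive density,

    ELPD = sum_c log p(y_c | y_-c),

estimated by Pareto-smoothed importance sampling over the posterior draws,
with exact refits (Gauss–Hermite marginal-likelihood ratios) for cells
whose importance weights are unreliable. A gene is called **zero-inflated
(ZI)** at threshold `k` when a ZI family beats every simpler nested family
by more than `k` standard errors of the pairwise ELPD difference
(`k` in 0–3; 1 SE is the usual operating point). The package also ships a
synthetic droplet-experiment generator, the power / type-I-error benchmark
machinery built on it, AIC/BIC utilities, and Matrix Market / CSV readers.

## Worked example

Simulate a small heterogeneous-tissue experiment (8 genes, 1,000 cells,
12 cell types) and classify each gene with cell type as a covariate:

```r
library(zicall)

sim <- gen_heartlike(heartlike_config(n_genes = 8, n_cells = 1000), seed = 42)
calls <- classify_genes(sim$counts,
                        total_umi = sim$covariates$total_umi,
                        groups    = sim$covariates$cell_type,
                        k_list = 1, seed = 42)
cbind(calls[, c("gene_id", "elpd_P", "elpd_NB", "elpd_ZIP", "elpd_ZINB",
                "chosen", "is_zi")],
      truth = sim$truth$family)
```

```
  gene_id    elpd_P   elpd_NB  elpd_ZIP elpd_ZINB chosen is_zi truth
1  gene_1 -1228.993 -1060.684 -1140.120 -1061.690     NB FALSE    NB
2  gene_2  -206.118  -206.397  -207.543  -208.312      P FALSE     P
3  gene_3 -1028.233  -987.426 -1008.570  -987.988     NB FALSE    NB
4  gene_4  -484.176  -472.003  -474.049  -471.897     NB FALSE    NB
5  gene_5  -686.150  -686.512  -687.148  -688.477      P FALSE     P
6  gene_6  -296.191  -295.375  -296.005  -296.607      P FALSE    NB
7  gene_7  -526.339  -484.281  -497.876  -485.240     NB FALSE    NB
8  gene_8  -893.650  -558.708  -653.064  -559.387     NB FALSE    NB
```

Each row shows the four ELPD scores (higher = better out-of-sample fit)
and the selected family at the 1 SE threshold. Overdispersed genes
(gene_1, _3, _7, _8) gain hundreds of ELPD units under NB and are called
NB; gene_4's ZINB edge (~0.1 ELPD) is far below 1 SE, so the ladder
demotes it to NB; gene_6 is a weakly overdispersed NB gene whose NB edge
(0.8 ELPD) is also within 1 SE of Poisson — the kind of under-calling the
SE threshold deliberately trades for calibration. No gene is called ZI,
and none is truly zero-inflated.

The same pipeline is available from the shell
(`inst/cli/zicall.R classify --counts <dir-or-csv> --metadata meta.tsv
--covariate cell_type --out results/`), writing `selection.tsv`,
`parameters.tsv` and a run log.

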