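#' Configuration for the droplet-scRNA-seq-like synthetic generator
#'
#' Defaults emulate a droplet single-cell experiment on a heterogeneous
#' mouse heart cell population: per-cell sequencing depths spanning
#' 746-17,302 with mean 3,819 UMIs/cell, per-gene expression rates spanning
#' 0.23-97.4 with mean 1.51 UMI/10K, 12 cell types with type-specific
#' rates, and per-gene NB overdispersion. The default family mix (P 0.383,
#' NB 0.577, ZIP 0.0147, ZINB 0.0252) follows the classification of 5,515
#' genes in that experiment at the 1 SE threshold.
#'
#' @param n_genes,n_cells Simulated matrix size.
#' @param depth_mean,depth_range Target mean and (min, max) of per-cell
#'   total UMI; depths are drawn from a range-truncated log-normal whose
#'   location is solved to hit `depth_mean`.
#' @param rate_mean,rate_range Same for per-gene base rates (UMI/10K).
#' @param n_cell_types Number of cell types (unequal random proportions).
#' @param type_effect_sd SD of per-gene, per-type log-rate deviations
#'   (0 gives a type-homogeneous population).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal law for the NB
#'   shape `r`.
#' @param family_props Named mixing proportions over P/NB/ZIP/ZINB truth.
#' @param pi0_range Range of the zero-inflation probability drawn for
#'   ZIP/ZINB truth genes.
#' @param depth_sdlog,rate_sdlog Log-scale spreads of the two truncated
#'   log-normals.
#' @param sex_gene If `TRUE`, gene 1 is made female-only: expressed at the
#'   mean rate in a random half of cells and silent in the other half.
#' @return A `zc_heartlike` config list.
#' @export
heartlike_config <- function(n_genes = 500, n_cells = 2000,
                             depth_mean = 3819, depth_range = c(746, 17302),
                             rate_mean = 1.51, rate_range = c(0.23, 97.4),
                             n_cell_types = 12, type_effect_sd = 1,
                             dispersion_meanlog = 0, dispersion_sdlog = 1,
                             family_props = c(P = 2112, NB = 3183,
                                              ZIP = 81, ZINB = 139) / 5515,
                             pi0_range = c(0.1, 0.9),
                             depth_sdlog = 0.6, rate_sdlog = 1.0,
                             sex_gene = FALSE) {
  stopifnot(depth_range[1] > 0, diff(depth_range) > 0,
            rate_range[1] > 0, diff(rate_range) > 0,
            depth_mean > depth_range[1], depth_mean < depth_range[2],
            rate_mean > rate_range[1], rate_mean < rate_range[2],
            n_cell_types >= 1, type_effect_sd >= 0,
            abs(sum(family_props) - 1) < 1e-8)
  structure(as.list(environment()), class = "zc_heartlike")
}

# Draw from a log-normal truncated to [a, b] with location solved so the
# truncated mean equals `target`.
rlnorm_trunc <- function(n, target, range, sdlog) {
  a <- range[1]; b <- range[2]
  tmean <- function(m) {
    za <- (log(a) - m) / sdlog; zb <- (log(b) - m) / sdlog
    denom <- pnorm(zb) - pnorm(za)
    exp(m + sdlog^2 / 2) *
      (pnorm(zb - sdlog) - pnorm(za - sdlog)) / denom
  }
  m <- stats::uniroot(function(m) tmean(m) - target,
                      lower = log(a) - 5 * sdlog,
                      upper = log(b) + 5 * sdlog, tol = 1e-10)$root
  u <- runif(n, pnorm((log(a) - m) / sdlog), pnorm((log(b) - m) / sdlog))
  qlnorm(u, meanlog = m, sdlog = sdlog)
}

#' Generate a synthetic heterogeneous-tissue UMI count matrix
#'
#' Draws cell depths and gene rates from range-truncated log-normals,
#' assigns cells to cell types with unequal proportions, gives each gene
#' type-specific rates `base * exp(dev)` with mean-centered Gaussian log
#' deviations, assigns each gene a truth family by the configured mixing
#' proportions, and samples counts through [sample_counts()]. Fully
#' reproducible from `seed`.
#'
#' @param config A [heartlike_config()].
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells integer matrix),
#'   `covariates` (data frame: `cell_id`, `cell_type`, `sex`, `total_umi`)
#'   and `truth` (data frame: `gene_id`, `family`, `base_rate`, `r`,
#'   `pi0`, `is_zi`; per-type rates in `attr(truth, "mu_by_type")`).
#' @export
gen_heartlike <- function(config = heartlike_config(), seed = 1L) {
  set.seed(as.integer(seed))
  G <- config$n_genes; C <- config$n_cells
  depths <- round(rlnorm_trunc(C, config$depth_mean, config$depth_range,
                               config$depth_sdlog))
  base <- rlnorm_trunc(G, config$rate_mean, config$rate_range,
                       config$rate_sdlog)
  k <- config$n_cell_types
  props <- rgamma(k, shape = 2); props <- props / sum(props)
  types <- factor(sample(paste0("type", seq_len(k)), C, replace = TRUE,
                         prob = props),
                  levels = paste0("type", seq_len(k)))
  sex <- factor(sample(c("F", "M"), C, replace = TRUE))
  # per-gene, per-type log-rate deviations, centered so E[exp(dev)] = 1
  dev <- matrix(rnorm(G * k, -config$type_effect_sd^2 / 2,
                      config$type_effect_sd), G, k)
  if (config$type_effect_sd == 0) dev[] <- 0
  mu_by_type <- base * exp(dev)
  dimnames(mu_by_type) <- list(paste0("gene_", seq_len(G)),
                               paste0("type", seq_len(k)))
  fam <- sample(names(config$family_props), G, replace = TRUE,
                prob = config$family_props)
  r <- ifelse(fam %in% c("NB", "ZINB"),
              rlnorm(G, config$dispersion_meanlog, config$dispersion_sdlog),
              NA_real_)
  pi0 <- ifelse(fam %in% c("ZIP", "ZINB"),
                runif(G, config$pi0_range[1], config$pi0_range[2]), 0)
  counts <- matrix(0L, G, C,
                   dimnames = list(rownames(mu_by_type),
                                   paste0("cell_", seq_len(C))))
  for (g in seq_len(G)) {
    counts[g, ] <- sample_counts(fam[g], mu_by_type[g, ], depths,
                                 groups = types, r = r[g], pi0 = pi0[g])
  }
  if (isTRUE(config$sex_gene)) {
    fam[1] <- "P"; r[1] <- NA_real_; pi0[1] <- 0
    mu_by_type[1, ] <- config$rate_mean
    counts[1, ] <- 0L
    female <- sex == "F"
    counts[1, female] <- sample_counts("P", config$rate_mean,
                                       depths[female])
  }
  truth <- data.frame(gene_id = rownames(counts), family = fam,
                      base_rate = base, r = r, pi0 = pi0,
                      is_zi = fam %in% c("ZIP", "ZINB"), row.names = NULL)
  attr(truth, "mu_by_type") <- mu_by_type
  covariates <- data.frame(cell_id = colnames(counts), cell_type = types,
                           sex = sex, total_umi = depths, row.names = NULL)
  list(counts = counts, covariates = covariates, truth = truth)
}

#' Simulate ZINB genes over a grid of known zero-inflation levels
#'
#' One gene per combination of base parameters and zero-inflation
#' probability, at a constant per-cell sequencing depth. Used to map power
#' to detect zero inflation as a function of `pi0` and depth.
#'
#' @param base_params Data frame with columns `mu` (UMI/10K) and `r`.
#' @param pi0_grid Zero-inflation probabilities in `(0, 1)`
#'   (default 0.1 to 0.9 by 0.1).
#' @param depth Constant per-cell total UMI (e.g. 10000 or 50000).
#' @param n_cells Cells per gene.
#' @param seed Integer seed.
#' @return List with `counts`, `covariates` and `truth` as in
#'   [gen_heartlike()].
#' @export
sim_fixed_pi0 <- function(base_params, pi0_grid = seq(0.1, 0.9, by = 0.1),
                          depth = 10000, n_cells = 2000, seed = 1L) {
  if (any(pi0_grid <= 0) || any(pi0_grid >= 1)) {
    stop("pi0_grid values must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  grid <- expand.grid(b = seq_len(nrow(base_params)), pi0 = pi0_grid)
  G <- nrow(grid)
  depths <- rep(depth, n_cells)
  counts <- matrix(0L, G, n_cells,
                   dimnames = list(sprintf("gene_%03d", seq_len(G)),
                                   paste0("cell_", seq_len(n_cells))))
  for (g in seq_len(G)) {
    counts[g, ] <- sample_counts("ZINB", base_params$mu[grid$b[g]], depths,
                                 r = base_params$r[grid$b[g]],
                                 pi0 = grid$pi0[g])
  }
  truth <- data.frame(gene_id = rownames(counts), family = "ZINB",
                      base_rate = base_params$mu[grid$b],
                      r = base_params$r[grid$b], pi0 = grid$pi0,
                      is_zi = TRUE, row.names = NULL)
  covariates <- data.frame(cell_id = colnames(counts),
                           total_umi = depths, row.names = NULL)
  list(counts = counts, covariates = covariates, truth = truth)
}

#' Re-simulate genes from their classification calls
#'
#' For each gene, draws counts from the family chosen at one SE threshold
#' using that family's fitted parameters — the "simulate what we called"
#' design that turns a classified dataset into a truth-labelled benchmark.
#'
#' @param calls A [classify_genes()] result (or subset).
#' @param params The matching fitted-parameter table
#'   (`attr(calls, "params")` by default).
#' @param k Which SE threshold's calls to simulate from.
#' @param total_umi Per-cell depths for the simulated cells.
#' @param groups Optional per-cell covariate; fitted group rates are used
#'   when present.
#' @param seed Integer seed.
#' @return List with `counts`, `covariates`, `truth`. Genes whose call is
#'   `"failed"` are skipped with a message.
#' @export
sim_from_calls <- function(calls, params = attr(calls, "params"), k = 0,
                           total_umi, groups = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  sub <- calls[calls$k == k, ]
  if (nrow(sub) == 0) stop("no calls at k = ", k)
  failed <- sub$chosen == "failed"
  if (any(failed)) {
    message(sum(failed), " gene(s) with failed calls skipped")
    sub <- sub[!failed, ]
  }
  C <- length(total_umi)
  counts <- matrix(0L, nrow(sub), C,
                   dimnames = list(sub$gene_id, paste0("cell_", seq_len(C))))
  r <- pi0 <- numeric(nrow(sub)); base <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    p <- params[params$gene_id == sub$gene_id[i] &
                params$family == sub$chosen[i], ]
    mu <- stats::setNames(p$mu, p$group)
    r[i] <- p$r[1]; pi0[i] <- p$pi0[1]; base[i] <- mean(p$mu)
    counts[i, ] <- sample_counts(sub$chosen[i],
                                 if (is.null(groups)) unname(mu[1]) else mu,
                                 total_umi, groups = groups,
                                 r = r[i], pi0 = pi0[i])
  }
  truth <- data.frame(gene_id = sub$gene_id, family = sub$chosen,
                      base_rate = base, r = r, pi0 = pi0,
                      is_zi = sub$chosen %in% c("ZIP", "ZINB"),
                      row.names = NULL)
  covariates <- data.frame(cell_id = colnames(counts), total_umi = total_umi,
                           row.names = NULL)
  if (!is.null(groups)) covariates$cell_type <- groups
  list(counts = counts, covariates = covariates, truth = truth)
}

#' Down-sample cells uniformly without replacement
#'
#' @param counts Genes x cells matrix.
#' @param n Number of cells to keep (`1 <= n <= C`).
#' @param seed Integer seed.
#' @param covariates Optional per-cell table subset identically.
#' @return The subset matrix, or a list `(counts, covariates)` when
#'   covariates are supplied.
#' @export
downsample_cells <- function(counts, n, seed = 1L, covariates = NULL) {
  if (n <= 0) stop("n must be positive")
  if (n > ncol(counts)) stop("n exceeds the number of cells")
  set.seed(as.integer(seed))
  idx <- sample.int(ncol(counts), n)
  out <- counts[, idx, drop = FALSE]
  if (is.null(covariates)) return(out)
  list(counts = out, covariates = covariates[idx, , drop = FALSE])
}

#' Fit NB and ZINB to every gene and tabulate both parameter sets
#'
#' The mis-specification study: fitting ZINB to data without zero
#' inflation shows how unstable the estimated `pi0` is, while fitting NB
#' to zero-inflated data recovers the marginal mean `(1 - pi0) * mu`.
#'
#' @param counts Genes x cells matrix.
#' @param truth Truth table as produced by the generators.
#' @param total_umi Per-cell depths (default column sums).
#' @param groups Optional per-cell covariate.
#' @param mode,prior,sampler Passed to [fit_gene()].
#' @param seed Integer seed.
#' @return Data frame, one row per gene x group: truth columns plus
#'   `nb_mu`, `nb_r`, `zinb_mu`, `zinb_r`, `zinb_pi0` and convergence
#'   flags.
#' @export
crossfit_nb_zinb <- function(counts, truth, total_umi = NULL, groups = NULL,
                             mode = "approx", prior = prior_spec(),
                             sampler = sampler_config(), seed = 1L) {
  stopifnot(all(truth$family %in% c("NB", "ZINB")))
  counts <- as.matrix(counts)
  if (is.null(total_umi)) total_umi <- colSums(counts)
  design <- design_spec(total_umi, groups = groups)
  rows <- list()
  for (g in seq_len(nrow(counts))) {
    y <- as.integer(counts[g, ])
    fnb <- fit_gene(y, design, "NB", prior = prior, mode = mode,
                    sampler = sampler, seed = seed + 2L * g)
    fzi <- fit_gene(y, design, "ZINB", prior = prior, mode = mode,
                    sampler = sampler, seed = seed + 2L * g + 1L)
    tr <- truth[truth$gene_id == rownames(counts)[g], ]
    rows[[g]] <- data.frame(
      gene_id = rownames(counts)[g], group = fnb$group_levels,
      true_family = tr$family, true_pi0 = tr$pi0, true_r = tr$r,
      nb_mu = unname(fnb$point$mu_by_group), nb_r = fnb$point$r,
      zinb_mu = unname(fzi$point$mu_by_group), zinb_r = fzi$point$r,
      zinb_pi0 = fzi$point$pi0,
      nb_converged = fnb$converged, zinb_converged = fzi$converged,
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' False/true positive rates and AUC for zero-inflation calls
#'
#' @param truth Truth table with `gene_id` and `is_zi`.
#' @param calls One threshold's calls with `gene_id`, `is_zi` and
#'   (optionally, for the AUC) `zi_score`.
#' @return A `zc_metrics` list: `fp_rate` (fraction of non-ZI truth called
#'   ZI), `tp_rate` (fraction of ZI truth called ZI; `NA` with a warning
#'   when there is no ZI truth), `auc` (rank AUC of `zi_score` against ZI
#'   truth; `NA` when either class is empty or the score is absent).
#' @export
classification_metrics <- function(truth, calls) {
  m <- merge(truth[, c("gene_id", "is_zi")],
             calls[, intersect(c("gene_id", "is_zi", "zi_score"),
                               names(calls))],
             by = "gene_id", suffixes = c("_true", "_call"))
  if (nrow(m) != nrow(truth)) stop("gene ids in truth and calls differ")
  n_pos <- sum(m$is_zi_true); n_neg <- sum(!m$is_zi_true)
  fp <- if (n_neg > 0) mean(m$is_zi_call[!m$is_zi_true]) else NA_real_
  tp <- if (n_pos > 0) mean(m$is_zi_call[m$is_zi_true]) else {
    warning("no zero-inflated truth genes; TP rate undefined")
    NA_real_
  }
  auc <- NA_real_
  if ("zi_score" %in% names(m) && n_pos > 0 && n_neg > 0) {
    sc <- m$zi_score
    sc[!is.finite(sc)] <- sign(sc[!is.finite(sc)]) * .Machine$double.xmax
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = m$is_zi_true, predictor = sc,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  }
  structure(list(fp_rate = fp, tp_rate = tp, auc = auc),
            class = "zc_metrics")
}

#' Simulate non-zero-inflated genes at constant depth
#'
#' The null benchmark for zero-inflation calling: genes drawn from P and
#' NB truth only (relative proportions taken from `config$family_props`),
#' with base rates and NB dispersions from the heart-like laws, at a
#' constant per-cell sequencing depth and no cell-type structure. Any
#' zero-inflation call on these genes is a false positive.
#'
#' @param n_genes,n_cells Matrix size.
#' @param depth Constant per-cell total UMI (default 10000).
#' @param config A [heartlike_config()] supplying the rate and dispersion
#'   laws and the P:NB mix.
#' @param seed Integer seed.
#' @return List with `counts`, `covariates`, `truth` as in
#'   [gen_heartlike()].
#' @export
sim_null_genes <- function(n_genes = 200, n_cells = 2000, depth = 10000,
                           config = heartlike_config(), seed = 1L) {
  set.seed(as.integer(seed))
  base <- rlnorm_trunc(n_genes, config$rate_mean, config$rate_range,
                       config$rate_sdlog)
  pnb <- config$family_props[c("P", "NB")]
  fam <- sample(c("P", "NB"), n_genes, replace = TRUE,
                prob = pnb / sum(pnb))
  r <- ifelse(fam == "NB",
              rlnorm(n_genes, config$dispersion_meanlog,
                     config$dispersion_sdlog), NA_real_)
  depths <- rep(depth, n_cells)
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(sprintf("gene_%04d", seq_len(n_genes)),
                                   paste0("cell_", seq_len(n_cells))))
  for (g in seq_len(n_genes)) {
    counts[g, ] <- sample_counts(fam[g], base[g], depths, r = r[g])
  }
  truth <- data.frame(gene_id = rownames(counts), family = fam,
                      base_rate = base, r = r, pi0 = 0, is_zi = FALSE,
                      row.names = NULL)
  covariates <- data.frame(cell_id = colnames(counts), total_umi = depths,
                           row.names = NULL)
  list(counts = counts, covariates = covariates, truth = truth)
}
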