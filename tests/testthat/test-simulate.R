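test_that("heart-like generator honors its depth and rate contract", {
  cfg <- heartlike_config(n_genes = 400, n_cells = 1500)
  sim <- gen_heartlike(cfg, seed = 5)
  depths <- sim$covariates$total_umi
  expect_lt(abs(mean(depths) - 3819) / 3819, 0.10)
  expect_gte(min(depths), 746)
  expect_lte(max(depths), 17302)
  expect_lte(max(sim$truth$base_rate), 97.4)
  expect_gte(min(sim$truth$base_rate), 0.23)
  expect_equal(nlevels(sim$covariates$cell_type), 12)
  expect_true(all(sim$truth$is_zi == (sim$truth$pi0 > 0)))
  # byte-identical reproduction from the same seed
  sim2 <- gen_heartlike(cfg, seed = 5)
  expect_identical(sim$counts, sim2$counts)
  expect_false(identical(sim$counts, gen_heartlike(cfg, seed = 6)$counts))
})

test_that("homogeneous configuration removes cell-type structure", {
  cfg <- heartlike_config(n_genes = 50, n_cells = 300, n_cell_types = 1,
                          type_effect_sd = 0)
  sim <- gen_heartlike(cfg, seed = 2)
  mu <- attr(sim$truth, "mu_by_type")
  expect_equal(unname(mu[, 1]), sim$truth$base_rate)
})

test_that("the female-only gene is expressed in exactly one sex", {
  cfg <- heartlike_config(n_genes = 30, n_cells = 400, sex_gene = TRUE)
  sim <- gen_heartlike(cfg, seed = 3)
  male <- sim$covariates$sex == "M"
  expect_true(all(sim$counts[1, male] == 0))
  expect_gt(sum(sim$counts[1, !male]), 0)
})

test_that("fixed-pi0 grid has the right cardinality and zero fraction", {
  base <- data.frame(mu = c(10, 20, 30, 40, 50), r = 2)
  sim <- sim_fixed_pi0(base, pi0_grid = seq(0.1, 0.9, 0.1), depth = 1e4,
                       n_cells = 100, seed = 1)
  expect_equal(nrow(sim$counts), 45)            # 5 base params x 9 levels
  expect_error(sim_fixed_pi0(base, pi0_grid = c(0, 0.5)))
  # closed-form zero probability at high depth and pi0
  sim2 <- sim_fixed_pi0(data.frame(mu = 50, r = 2), pi0_grid = 0.9,
                        depth = 5e4, n_cells = 10000, seed = 2)
  p0 <- 0.9 + 0.1 * prob_zero("NB", 50 * 5, r = 2)
  expect_lt(abs(mean(sim2$counts[1, ] == 0) - p0), 0.02)
})

test_that("resimulation from calls preserves the call bookkeeping", {
  set.seed(91)
  depths <- rep(8000, 600)
  counts <- rbind(
    t(sapply(1:3, function(i)
      sample_counts("ZINB", 40, depths, r = 2, pi0 = 0.6))),
    t(sapply(1:5, function(i) sample_counts("P", 3, depths)))
  )
  rownames(counts) <- paste0("g", 1:8)
  calls <- classify_fast(counts, total_umi = depths, k_list = 1)
  sim <- sim_from_calls(calls, k = 1, total_umi = depths, seed = 4)
  expect_equal(nrow(sim$counts), sum(calls$k == 1 & calls$chosen != "failed"))
  expect_equal(table(sim$truth$family)[names(table(calls$chosen))],
               table(calls$chosen)[names(table(calls$chosen))])
  # all-Poisson calls yield a zero-inflation-free truth
  calls_p <- calls; calls_p$chosen <- "P"
  simp <- sim_from_calls(calls_p, k = 1, total_umi = depths, seed = 5)
  expect_equal(sum(simp$truth$is_zi), 0)
})

test_that("cell down-sampling subsets columns and covariates together", {
  m <- matrix(seq_len(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  cov <- data.frame(cell_id = colnames(m), total_umi = colSums(m))
  out <- downsample_cells(m, 6, seed = 2, covariates = cov)
  expect_equal(ncol(out$counts), 6)
  expect_identical(colnames(out$counts), out$covariates$cell_id)
  full <- downsample_cells(m, 10, seed = 2)
  expect_setequal(colnames(full), colnames(m))
  single <- downsample_cells(m, 1, seed = 1)
  expect_equal(ncol(single), 1)
  expect_error(downsample_cells(m, 0))
  expect_error(downsample_cells(m, 11))
})

test_that("classification metrics match hand computation and the null AUC", {
  truth <- data.frame(gene_id = paste0("g", 1:8),
                      is_zi = rep(c(TRUE, FALSE), each = 4))
  calls <- data.frame(gene_id = paste0("g", 1:8),
                      is_zi = truth$is_zi,
                      zi_score = ifelse(truth$is_zi, 5, -5))
  m <- classification_metrics(truth, calls)
  expect_equal(m$fp_rate, 0)
  expect_equal(m$tp_rate, 1)
  expect_equal(m$auc, 1)
  calls$is_zi <- FALSE
  m2 <- classification_metrics(truth, calls)
  expect_equal(m2$fp_rate, 0)
  expect_equal(m2$tp_rate, 0)
  # random scores on balanced truth give AUC near 1/2
  set.seed(92)
  n <- 1000
  truth_n <- data.frame(gene_id = seq_len(n), is_zi = rep(c(TRUE, FALSE), n / 2))
  calls_n <- data.frame(gene_id = seq_len(n), is_zi = FALSE,
                        zi_score = rnorm(n))
  expect_lt(abs(classification_metrics(truth_n, calls_n)$auc - 0.5), 0.05)
  expect_warning(classification_metrics(
    data.frame(gene_id = "a", is_zi = FALSE),
    data.frame(gene_id = "a", is_zi = FALSE)))
})

test_that("ZINB cross-fit recovers the NB marginal mean identity", {
  set.seed(93)
  depths <- rep(10000, 3000)
  truth <- data.frame(gene_id = paste0("g", 1:4),
                      family = rep(c("NB", "ZINB"), 2),
                      pi0 = c(0, 0.4, 0, 0.4), r = 2)
  counts <- t(sapply(1:4, function(i)
    sample_counts(truth$family[i], 25, depths, r = 2, pi0 = truth$pi0[i])))
  rownames(counts) <- truth$gene_id
  est <- crossfit_nb_zinb(counts, truth, total_umi = depths,
                          sampler = fast_sampler, seed = 6)
  # NB fit on ZINB truth recovers the marginal mean (1 - pi0) * mu
  zi_rows <- est$true_family == "ZINB"
  expect_lt(max(abs(est$nb_mu[zi_rows] - 0.6 * 25) / (0.6 * 25)), 0.1)
  expect_lt(max(abs(est$nb_mu[!zi_rows] - 25) / 25), 0.1)
  # correctly-specified ZINB fit recovers pi0
  expect_lt(max(abs(est$zinb_pi0[zi_rows] - 0.4)), 0.1)
})
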