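test_that("posterior recovers a Poisson rate with calibrated uncertainty", {
  set.seed(41)
  d <- const_design(2000)
  y <- sample_counts("P", 10, d$total_umi)
  f <- fit_gene(y, d, "P", sampler = fast_sampler, seed = 1)
  expect_true(f$converged)
  mu_draws <- exp(f$draws[, 1])
  expect_lt(abs(mean(mu_draws) - 10), 3 * sd(mu_draws))
})

test_that("ZINB recovery at high expression pins down pi0", {
  set.seed(42)
  d <- const_design(5000)
  y <- sample_counts("ZINB", 20, d$total_umi, r = 2, pi0 = 0.5)
  f <- fit_gene(y, d, "ZINB", sampler = fast_sampler, seed = 2)
  expect_true(f$converged)
  expect_lt(abs(f$point$pi0 - 0.5), 0.1)
  expect_lt(abs(f$point$mu_by_group[[1]] - 20) / 20, 0.25)
})

test_that("an all-zero gene is handled, not raised", {
  d <- const_design(500)
  y <- rep(0L, 500)
  fp <- fit_gene(y, d, "P", sampler = fast_sampler, seed = 3)
  expect_lt(fp$point$mu_by_group[[1]], 0.1)   # prior-dominated lower bound
  fz <- fit_gene(y, d, "ZINB", sampler = fast_sampler, seed = 3)
  expect_false(fz$converged)                  # flagged non-identifiable
  expect_true(fz$nonidentifiable)
})

test_that("dimension mismatches and bad inputs error", {
  d <- const_design(50)
  expect_error(fit_gene(rep(0L, 49), d, "P"))
  expect_error(fit_gene(rep(-1L, 50), d, "P"))
  expect_error(design_spec(c(0, 100)))
})

test_that("point estimates are deterministic transforms of the draws", {
  d <- const_design(200)
  set.seed(44)
  y <- sample_counts("NB", 5, d$total_umi, r = 1)
  f <- fit_gene(y, d, "NB", sampler = fast_sampler, seed = 4)
  # posterior mean of exp(beta), recomputed by hand
  expect_equal(unname(f$point$mu_by_group), mean(exp(f$draws[, 1])))
  expect_equal(f$point$r, mean(exp(f$draws[, 2])))
  expect_identical(f$point$pi0, 0)            # NB has no zero component
  f2 <- f; f2$draws[, 1] <- log(2)
  expect_equal(unname(point_estimates(f2)$mu_by_group[1]), 2)
})

test_that("pointwise log likelihoods match direct pmf evaluation", {
  d <- design_spec(c(5000, 10000, 20000))
  y <- c(0L, 2L, 7L)
  f <- fit_gene(c(1L, 2L, 3L, 0L, 1L), const_design(5), "P",
                sampler = fast_sampler, seed = 5)
  # single known draw, evaluated on a fresh design
  f$draws <- matrix(log(10), 1, 1, dimnames = list(NULL, "beta[1]"))
  ll <- loglik_pointwise(f, y, d)
  expect_equal(drop(ll), zi_logpmf("P", y, 10 * d$total_umi / 1e4))
  # ZINB draws with pi0 = 0 equal NB values for the same (mu, r) draws
  fz <- fit_gene(y, d, "ZINB", sampler = fast_sampler, seed = 6)
  fz$draws[, "logit_pi0"] <- -Inf
  fn <- fz; fn$family <- "NB"
  fn$draws <- fz$draws[, 1:2, drop = FALSE]
  expect_equal(loglik_pointwise(fz, y, d), loglik_pointwise(fn, y, d))
  expect_error(loglik_pointwise(fz, y[1:2], d))
})

test_that("analytic posterior gradients match numerical differentiation", {
  set.seed(46)
  n <- 60
  types <- factor(sample(c("a", "b"), n, replace = TRUE))
  d <- design_spec(round(runif(n, 3000, 15000)), groups = types)
  prior <- prior_spec()
  for (fam in count_families) {
    y <- sample_counts(fam, c(a = 2, b = 10), d$total_umi, groups = types,
                       r = 1.5, pi0 = if (is_zi_family(fam)) 0.3 else 0)
    cd <- zicall:::collapse_design(y, d)
    theta <- zicall:::init_theta(fam, y, d, cd) + rnorm(5)[seq_len(
      2 + zicall:::has_dispersion(fam) + zicall:::has_zi(fam))] * 0.3
    ga <- zicall:::log_post_grad(theta, fam, cd, 2, prior)
    gn <- pracma::grad(function(th)
      zicall:::log_post(th, fam, cd, 2, prior), theta)
    expect_lt(max(abs(ga - gn)) / max(1, max(abs(gn))), 1e-5)
  }
})

test_that("mcmc mode agrees with the Laplace approximation when well identified", {
  set.seed(47)
  d <- const_design(1000)
  y <- sample_counts("NB", 8, d$total_umi, r = 2)
  fa <- fit_gene(y, d, "NB", mode = "approx", sampler = fast_sampler, seed = 7)
  fm <- fit_gene(y, d, "NB", mode = "mcmc", sampler = sampler_config(), seed = 7)
  expect_true(fm$converged)
  expect_true(all(fm$diagnostics$rhat < 1.05))
  expect_lt(abs(fa$point$mu_by_group[[1]] - fm$point$mu_by_group[[1]]) /
              fm$point$mu_by_group[[1]], 0.1)
  expect_lt(abs(fa$point$r - fm$point$r) / fm$point$r, 0.1)
})

test_that("accounting for cell type reduces the fitted overdispersion", {
  # overdispersion = 1/r under the mean-shape parameterization: removing
  # type-driven heterogeneity from the residual raises the fitted shape
  set.seed(48)
  n <- 1200
  types <- factor(sample(paste0("t", 1:4), n, replace = TRUE))
  depths <- rep(8000, n)
  d0 <- design_spec(depths)
  d1 <- design_spec(depths, groups = types)
  r_hat <- replicate(20, {
    mu <- setNames(exp(log(6) + rnorm(4, 0, 1)), paste0("t", 1:4))
    y <- sample_counts("NB", mu, depths, groups = types, r = 5)
    c(with = fit_gene(y, d1, "NB", sampler = fast_sampler, seed = 8)$point$r,
      without = fit_gene(y, d0, "NB", sampler = fast_sampler, seed = 8)$point$r)
  })
  expect_lt(median(1 / r_hat["with", ]), median(1 / r_hat["without", ]))
})
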