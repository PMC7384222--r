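test_that("log pmfs match closed forms and reduce across the nesting order", {
  expect_equal(zi_logpmf("P", 0, mu = 1), -1)
  expect_equal(zi_logpmf("NB", 0, mu = 2, r = 2), 2 * log(0.5))
  # pi0 = 0 collapses each ZI family onto its base family, pointwise
  y <- 0:25
  expect_equal(zi_logpmf("ZIP", y, mu = 3.2, pi0 = 0),
               zi_logpmf("P", y, mu = 3.2))
  expect_equal(zi_logpmf("ZINB", y, mu = 2.5, r = 1.7, pi0 = 0),
               zi_logpmf("NB", y, mu = 2.5, r = 1.7))
  # NB converges to P as r -> infinity
  expect_equal(zi_logpmf("NB", 4, mu = 1, r = 1e6),
               zi_logpmf("P", 4, mu = 1), tolerance = 1e-4)
})

test_that("pmfs normalize to 1 over the support", {
  y <- 0:5000
  cases <- list(
    list(fam = "P", mu = 8, r = NULL, pi0 = NULL),
    list(fam = "NB", mu = 12, r = 0.4, pi0 = NULL),
    list(fam = "ZIP", mu = 20, r = NULL, pi0 = 0.35),
    list(fam = "ZINB", mu = 15, r = 2, pi0 = 0.7)
  )
  for (cs in cases) {
    p <- exp(zi_logpmf(cs$fam, y, cs$mu, r = cs$r, pi0 = cs$pi0))
    expect_lt(abs(sum(p) - 1), 1e-8)
  }
})

test_that("pmf arguments are validated", {
  expect_error(zi_logpmf("P", -1, mu = 1))
  expect_error(zi_logpmf("P", 0, mu = 0))
  expect_error(zi_logpmf("NB", 0, mu = 1, r = -2))
  expect_error(zi_logpmf("ZIP", 0, mu = 1, pi0 = 1.2))
  expect_error(zi_logpmf("NB", 0, mu = 1))       # r required
  expect_error(zi_logpmf("XX", 0, mu = 1))
})

test_that("prob_zero matches closed forms and is monotone", {
  expect_equal(prob_zero("P", 1), exp(-1))
  expect_equal(prob_zero("NB", 2, r = 2), 0.25)
  expect_equal(prob_zero("ZINB", 5, r = 1, pi0 = 1), 1)
  mu <- seq(0.5, 20, length.out = 30)
  expect_true(all(diff(prob_zero("NB", mu, r = 1.3)) < 0))
  p0 <- vapply(seq(0, 1, 0.1), function(p)
    prob_zero("ZIP", 2, pi0 = p), numeric(1))
  expect_true(all(diff(p0) >= 0))
})

test_that("sampler reproduces the target moments and zero fraction", {
  set.seed(11)
  y <- sample_counts("NB", 5, rep(10000, 50000), r = 2)
  expect_lt(abs(mean(y) - 5) / 5, 0.02)
  expect_lt(abs(var(y) - 17.5) / 17.5, 0.05)
  set.seed(12)
  z <- sample_counts("ZIP", 10, rep(10000, 50000), pi0 = 0.5)
  expect_lt(abs(mean(z == 0) - (0.5 + 0.5 * exp(-10))), 0.01)
  # obligate zeros only
  expect_true(all(sample_counts("ZIP", 5, rep(1e4, 100), pi0 = 1) == 0))
})

test_that("sampler empirical pmf matches the analytic pmf", {
  set.seed(21)
  n <- 1e5
  y <- sample_counts("ZINB", 8, rep(10000, n), r = 1.5, pi0 = 0.4)
  sup <- 0:max(y)
  p <- exp(zi_logpmf("ZINB", sup, 8, r = 1.5, pi0 = 0.4))
  # pool the sparse upper tail so expected counts stay above 5
  obs <- tabulate(y + 1L, nbins = length(sup))
  keep <- which(n * p >= 5)
  obs_b <- c(obs[keep], n - sum(obs[keep]))
  p_b <- c(p[keep], 1 - sum(p[keep]))
  gof <- suppressWarnings(chisq.test(obs_b, p = p_b))
  expect_gt(gof$p.value, 0.001)
})

test_that("group-specific rates are honored and unknown labels rejected", {
  set.seed(31)
  g <- rep(c("a", "b"), each = 4000)
  y <- sample_counts("P", c(a = 2, b = 40), rep(10000, 8000), groups = g)
  expect_lt(abs(mean(y[g == "a"]) - 2), 0.2)
  expect_gt(mean(y[g == "b"]), 30)
  expect_error(sample_counts("P", c(a = 1), rep(1e4, 2),
                             groups = c("a", "zzz")), "zzz")
})

test_that("family metadata encodes the nesting partial order", {
  expect_equal(family_rank(c("P", "NB", "ZIP", "ZINB")), c(0L, 1L, 1L, 2L))
  expect_setequal(simpler_families("ZINB"), c("P", "NB", "ZIP"))
  expect_equal(simpler_families("NB"), "P")
  expect_false("ZIP" %in% simpler_families("NB"))  # NB, ZIP not nested
  expect_true(all(is_zi_family(c("ZIP", "ZINB"))))
  expect_false(any(is_zi_family(c("P", "NB"))))
})
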