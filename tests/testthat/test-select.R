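mk_elpd <- function(pw, family) {
  structure(list(family = family, pointwise = pw, elpd = sum(pw),
                 se = sd(pw) * sqrt(length(pw)), converged = TRUE),
            class = "zc_elpd")
}

elpd_set <- function(pw_list) {
  out <- Map(mk_elpd, pw_list, names(pw_list))
  names(out) <- names(pw_list)
  out
}

test_that("the simplest family wins all exact ties", {
  pw <- rep(-1.3, 40)
  el <- elpd_set(list(P = pw, NB = pw, ZIP = pw, ZINB = pw))
  for (k in 0:3) {
    sel <- select_family(el, k)
    expect_identical(sel$chosen, "P")
    expect_false(sel$is_zi)
  }
})

test_that("a decisively better complex model survives every threshold", {
  set.seed(71)
  base <- rnorm(60, -2, 0.1)
  el <- elpd_set(list(P = base - 3, NB = base - 2, ZIP = base - 2,
                      ZINB = base))
  for (k in 0:3) expect_identical(select_family(el, k)$chosen, "ZINB")
})

test_that("selection is idempotent and monotone in the threshold", {
  set.seed(72)
  for (rep in 1:20) {
    pw <- lapply(1:4, function(i) rnorm(30, -2, 0.5))
    names(pw) <- count_families
    el <- elpd_set(pw)
    ranks <- vapply(c(0, 1, 2, 3), function(k) {
      ch <- select_family(el, k)$chosen
      family_rank(ch)
    }, integer(1))
    expect_true(all(diff(ranks) <= 0))
    # repeated application returns the same call
    s1 <- select_family(el, 1)
    expect_identical(select_family(el, 1)$chosen, s1$chosen)
  }
})

test_that("failed fits are excluded and k is validated", {
  pw <- rnorm(30, -2, 0.2)
  el <- elpd_set(list(P = pw, NB = pw + 0.01, ZIP = pw, ZINB = pw))
  el$NB$converged <- FALSE
  expect_false(select_family(el, 0)$chosen == "NB")
  expect_error(select_family(el, -1))
  el_all_failed <- lapply(el, function(e) { e$converged <- FALSE; e })
  expect_identical(select_family(el_all_failed, 1)$chosen, "failed")
})

test_that("classification table is monotone in k and flags planted signal", {
  set.seed(73)
  n_cells <- 1000
  depths <- rep(8000, n_cells)
  counts <- rbind(
    t(sapply(1:5, function(i)
      sample_counts("ZINB", 30, depths, r = 2, pi0 = 0.6))),
    t(sapply(1:10, function(i) sample_counts("P", runif(1, 1, 5), depths)))
  )
  rownames(counts) <- c(paste0("zi_", 1:5), paste0("null_", 1:10))
  calls <- classify_fast(counts, total_umi = depths, k_list = 0:3)
  n_zi <- tapply(calls$is_zi, calls$k, sum)
  expect_true(all(diff(n_zi) <= 0))            # fewer ZI calls as k grows
  planted <- calls[calls$k == 1 & grepl("^zi_", calls$gene_id), ]
  expect_true(all(planted$is_zi))
  expect_error(classify_genes(matrix(integer(0), 0, 0)))
})

test_that("information criteria follow their definitions and nesting", {
  set.seed(74)
  d <- const_design(100)
  y <- sample_counts("NB", 5, d$total_umi, r = 1)
  ic_p <- information_criteria(y, d, "P")
  expect_equal(ic_p$aic, 2 - 2 * ic_p$loglik)
  expect_equal(ic_p$bic, log(100) - 2 * ic_p$loglik)
  ic_nb <- information_criteria(y, d, "NB")
  expect_gte(ic_nb$loglik, ic_p$loglik)        # NB nests P
  # independent oracle: NB maximum likelihood via MASS::glm.nb
  off <- d$offset
  suppressWarnings({
    ref <- MASS::glm.nb(y ~ 1 + offset(off))
  })
  expect_lt(abs(ic_nb$loglik - as.numeric(logLik(ref))), 0.01)
})

test_that("BIC selects the simple model at least as often as AIC", {
  set.seed(75)
  d <- const_design(2000)
  picks <- t(replicate(30, {
    y <- sample_counts("P", 3, d$total_umi)
    aic <- c(P = information_criteria(y, d, "P")$aic,
             NB = information_criteria(y, d, "NB")$aic)
    bic <- c(P = information_criteria(y, d, "P")$bic,
             NB = information_criteria(y, d, "NB")$bic)
    c(aic_p = names(which.min(aic)) == "P",
      bic_p = names(which.min(bic)) == "P")
  }))
  expect_gte(sum(picks[, "bic_p"]), sum(picks[, "aic_p"]))
})
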