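## Pareto-smoothed importance sampling LOO.
##
## Importance ratios target the leave-one-out posterior p(theta | y_-c).
## Draws may come from the posterior itself (MCMC mode, raw log ratio
## -loglik_c) or from a Laplace proposal q (approx mode), in which case the
## per-draw correction log p(theta|y) - log q(theta) stored in the fit is
## added. Tail weights are smoothed by a generalized Pareto fit (empirical
## Bayes grid estimator of Zhang & Stephens 2009); the tail shape k-hat is
## the reliability score, with exact refitting as fallback when it exceeds
## the threshold.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances x > 0; returns shape k (heavy tail
# when k > 0) and scale sigma.
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort.int(x)
  if (n < 5 || x[n] <= 0 || x[n] == x[1]) {
    return(list(k = NA_real_, sigma = NA_real_))
  }
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- min(x[x > 0])
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  khat_j <- vapply(b, function(bj) -mean(log1p(-bj * x)), numeric(1))
  lik <- n * (log(b / khat_j) + khat_j - 1)
  w <- exp(lik - logsumexp(lik))
  bhat <- sum(b * w)
  k <- mean(log1p(-bhat * x))
  sigma <- -k / bhat
  # weak prior on k toward 0.5 regularizes small tails
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of raw log importance weights; returns the smoothed,
# max-normalized log weights and the Pareto tail shape.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  ntail <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (ntail < 5 || stats::sd(lw) < 1e-12) {
    return(list(lw = lw, khat = -Inf))
  }
  ord <- order(lw)
  cut_idx <- S - ntail
  cutoff <- lw[ord[cut_idx]]
  tail_idx <- ord[(cut_idx + 1):S]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, khat = -Inf))
  # replace tail by expected order statistics of the fitted GPD
  qq <- qgpd((seq_len(ntail) - 0.5) / ntail, fit$k, fit$sigma)
  sm <- log(exp(cutoff) + qq)
  sm <- pmin(sm, 0)                       # never exceed max raw weight
  lw[tail_idx[order(lw[tail_idx])]] <- sm
  list(lw = lw - max(lw), khat = fit$k)
}

#' Leave-one-out expected log predictive density for one fit
#'
#' Estimates `ELPD = sum_c log p(y_c | y_-c)` by Pareto-smoothed importance
#' sampling over the posterior draws of `fit`. Cells whose Pareto tail
#' shape exceeds `khat_threshold` are, under
#' `refit_policy = "exact_fallback"`, recomputed exactly by refitting the
#' model without that cell and averaging the predictive density over the
#' refit draws. Cells with identical (count, offset, group) share one
#' computation.
#'
#' @param fit A `zc_fit` from [fit_gene()].
#' @param y,design The data the fit was computed from.
#' @param refit_policy `"exact_fallback"` (default) or `"none"`.
#' @param khat_threshold Reliability threshold for the tail shape
#'   (default 0.7).
#' @return A `zc_elpd` list: `family`, `pointwise` (per-cell log predictive
#'   density), `elpd`, `se` (`sd(pointwise) * sqrt(C)`), `khat` per cell,
#'   `n_refit`, `converged`.
#' @export
elpd_loo <- function(fit, y, design,
                     refit_policy = c("exact_fallback", "none"),
                     khat_threshold = 0.7) {
  refit_policy <- match.arg(refit_policy)
  if (nrow(fit$draws) < 2) stop("need at least 2 posterior draws")
  cd <- collapse_design(y, design)
  llk <- loglik_mat(fit$draws, fit$family, cd, fit$n_groups)
  pw_key <- numeric(cd$n_keys)
  khat_key <- numeric(cd$n_keys)
  for (j in seq_len(cd$n_keys)) {
    lw_raw <- fit$lw0 - llk[, j]
    sm <- psis_smooth(lw_raw)
    pw_key[j] <- logsumexp(sm$lw + llk[, j]) - logsumexp(sm$lw)
    khat_key[j] <- sm$khat
  }
  n_refit <- 0L
  if (refit_policy == "exact_fallback") {
    bad <- which(is.finite(khat_key) & khat_key > khat_threshold)
    # deterministic quadrature refit when the dimension allows, otherwise
    # average the predictive density over refit draws
    use_quad <- ncol(fit$draws) <= 4
    lm_full <- if (use_quad && length(bad)) {
      marginal_loglik(fit$family, cd, fit$n_groups, fit$prior, nodes = 12)
    } else NULL
    for (j in bad) {
      pw_key[j] <- if (use_quad) {
        lm_full - marginal_loglik(fit$family, drop_one_key(cd, j),
                                  fit$n_groups, fit$prior, nodes = 12)
      } else {
        exact_loo_one(fit, y, design, which(cd$map == j)[1])
      }
      n_refit <- n_refit + 1L
    }
  }
  pointwise <- pw_key[cd$map]
  structure(list(
    family = fit$family,
    pointwise = pointwise,
    elpd = sum(pointwise),
    se = stats::sd(pointwise) * sqrt(length(pointwise)),
    khat = khat_key[cd$map],
    n_refit = n_refit,
    converged = fit$converged
  ), class = "zc_elpd")
}

# log p(y_c | y_-c) by refitting without cell c and averaging the
# predictive density over the refit's (importance-corrected) draws.
exact_loo_one <- function(fit, y, design, c_drop) {
  keep <- setdiff(seq_along(y), c_drop)
  sub_design <- design_spec(design$total_umi[keep],
                            groups = if (fit$n_groups > 1)
                              as.character(design$groups[keep]) else NULL,
                            offset_divisor = design$offset_divisor)
  # keep the dropped cell's group level even if now empty
  if (fit$n_groups > 1) {
    sub_design$groups <- factor(as.character(design$groups[keep]),
                                levels = fit$group_levels)
  }
  refit <- fit_gene(y[keep], sub_design, fit$family, prior = fit$prior,
                    mode = fit$mode, sampler = fit$sampler,
                    seed = fit$seed + 7L * c_drop)
  th <- refit$draws
  ng <- fit$n_groups
  g <- as.integer(factor(as.character(design$groups[c_drop]),
                         levels = fit$group_levels))
  mu <- exp(design$offset[c_drop] + th[, g])
  ll_c <- if (has_dispersion(fit$family)) {
    dnbinom(y[c_drop], size = exp(th[, ng + 1]), mu = mu, log = TRUE)
  } else {
    dpois(y[c_drop], lambda = mu, log = TRUE)
  }
  if (has_zi(fit$family)) {
    pi0 <- plogis(th[, ncol(th)])
    ll_zi <- log1p(-pi0) + ll_c
    if (y[c_drop] == 0) {
      m <- pmax(log(pi0), ll_zi)
      ll_c <- m + log(exp(log(pi0) - m) + exp(ll_zi - m))
    } else ll_c <- ll_zi
  }
  logsumexp(refit$lw0 + ll_c) - logsumexp(refit$lw0)
}

#' Exact brute-force LOO by refitting once per cell
#'
#' Reference implementation of `ELPD = sum_c log p(y_c | y_-c)`: one full
#' refit per left-out cell (cells with identical data are refit once).
#' With `method = "quadrature"` (the default for models with at most 4
#' parameters) each predictive density is the ratio of marginal
#' likelihoods `m(y) / m(y_-c)`, both integrated deterministically by
#' adaptive Gauss-Hermite quadrature around the refit posterior mode;
#' `"draws"` averages the predictive density over refit posterior draws.
#' Intended for validating the importance-sampling estimate on small
#' problems.
#'
#' @inheritParams elpd_loo
#' @param method `"quadrature"`, `"draws"` or `"auto"` (quadrature when
#'   dimension allows).
#' @param nodes Gauss-Hermite nodes per dimension (default 20).
#' @return A `zc_elpd` list.
#' @export
elpd_loo_exact <- function(fit, y, design,
                           method = c("auto", "quadrature", "draws"),
                           nodes = 20) {
  method <- match.arg(method)
  n_par <- ncol(fit$draws)
  if (method == "auto") {
    method <- if (n_par <= 4) "quadrature" else "draws"
  }
  if (method == "quadrature" && n_par > 4) {
    stop("quadrature oracle limited to models with <= 4 parameters")
  }
  cd <- collapse_design(y, design)
  if (method == "quadrature") {
    lm_full <- marginal_loglik(fit$family, cd, fit$n_groups, fit$prior,
                               nodes)
    pw_key <- vapply(seq_len(cd$n_keys), function(j) {
      lm_full - marginal_loglik(fit$family, drop_one_key(cd, j),
                                fit$n_groups, fit$prior, nodes)
    }, numeric(1))
  } else {
    pw_key <- vapply(seq_len(cd$n_keys), function(j) {
      exact_loo_one(fit, y, design, which(cd$map == j)[1])
    }, numeric(1))
  }
  pointwise <- pw_key[cd$map]
  structure(list(
    family = fit$family, pointwise = pointwise, elpd = sum(pointwise),
    se = stats::sd(pointwise) * sqrt(length(pointwise)),
    khat = rep(NA_real_, length(pointwise)),
    n_refit = cd$n_keys, converged = fit$converged
  ), class = "zc_elpd")
}

# log marginal likelihood log m(y) = log integral p(y|theta) p(theta)
# d(theta) by adaptive Gauss-Hermite quadrature: nodes are centered at the
# posterior mode and rotated/scaled by the Cholesky factor of the Laplace
# covariance. Deterministic; feasible for <= 4 parameters.
marginal_loglik <- function(family, cd, n_groups, prior, nodes = 20) {
  nm <- par_layout(family, n_groups)
  d <- length(nm)
  init <- rep(0, d); names(init) <- nm
  # data-driven init as in fit_gene, from the collapsed representation
  for (g in seq_len(n_groups)) {
    i <- cd$gidx == g
    init[g] <- if (any(i)) {
      log((sum(cd$w[i] * cd$y[i]) + 0.5) / sum(cd$w[i] * exp(cd$offset[i])))
    } else 0
  }
  if (has_dispersion(family)) init[n_groups + 1] <- 0
  if (has_zi(family)) init[d] <- qlogis(0.1)
  lap <- laplace_fit(family, cd, n_groups, prior, init)
  gh <- pracma::gaussHermite(nodes)
  grids <- replicate(d, seq_len(nodes), simplify = FALSE)
  idx <- as.matrix(expand.grid(grids))
  z <- matrix(gh$x[idx], ncol = d)
  lw <- rowSums(matrix(log(gh$w)[idx], ncol = d)) + rowSums(z^2)
  L <- safe_chol(lap$Sigma)
  theta <- sweep(sqrt(2) * z %*% L, 2, lap$mode, `+`)
  lp <- log_post_mat(theta, family, cd, n_groups, prior)
  d / 2 * log(2) + sum(log(diag(L))) + logsumexp(lw + lp)
}

# remove one cell's worth of weight from key j of a collapsed design
drop_one_key <- function(cd, j) {
  cd$w[j] <- cd$w[j] - 1
  if (cd$w[j] == 0) {
    keep <- -j
    cd$y <- cd$y[keep]; cd$offset <- cd$offset[keep]
    cd$gidx <- cd$gidx[keep]; cd$w <- cd$w[keep]
    cd$n_keys <- cd$n_keys - 1L
  }
  cd
}
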