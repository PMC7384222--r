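#' Design for a per-gene count GLM
#'
#' Bundles the per-cell exposure and optional categorical covariate used by
#' [fit_gene()]. The log mean for cell `c` is `offset_c + beta_{group(c)}`
#' with `offset_c = log(total_umi_c / offset_divisor)`, so `exp(beta)` is
#' the group expression rate in UMI per `offset_divisor` total UMI
#' (UMI/10K by default). Groups are cell-means coded: one log-rate
#' coefficient per level, no global intercept.
#'
#' @param total_umi Positive per-cell total UMI counts.
#' @param groups Optional per-cell categorical covariate (cell type, sex);
#'   `NULL` means a single shared rate (offset-only model).
#' @param offset_divisor Library size defining the rate unit (default 1e4).
#' @return A `zc_design` list with `offset`, `groups` (factor), `n_cells`,
#'   `total_umi`, `offset_divisor`.
#' @export
design_spec <- function(total_umi, groups = NULL, offset_divisor = 1e4) {
  if (any(total_umi <= 0)) stop("total_umi must be positive")
  n <- length(total_umi)
  groups <- if (is.null(groups)) factor(rep("all", n)) else factor(groups)
  if (length(groups) != n) stop("groups length must equal number of cells")
  if (n < nlevels(groups) + 2) stop("need at least n_groups + 2 cells")
  structure(list(
    offset = log(total_umi / offset_divisor),
    groups = groups,
    n_cells = n,
    total_umi = total_umi,
    offset_divisor = offset_divisor
  ), class = "zc_design")
}

#' Priors for the Bayesian count GLM
#'
#' Weakly informative proper priors: Normal(0, `beta_scale`^2) on each
#' log-rate coefficient, Exponential(`r_prior_rate`) on the inverse shape
#' `1/r`, Normal(0, `pi0_logit_scale`^2) on the zero-inflation logit
#' intercept. These stabilize fits for all-zero and very low-count genes.
#'
#' @param beta_scale Prior sd of log-rate coefficients (default 5).
#' @param r_prior_rate Rate of the exponential prior on `1/r` (default 1).
#' @param pi0_logit_scale Prior sd of logit `pi0` (default 1.5).
#' @return A `zc_prior` list.
#' @export
prior_spec <- function(beta_scale = 5, r_prior_rate = 1, pi0_logit_scale = 1.5) {
  stopifnot(beta_scale > 0, r_prior_rate > 0, pi0_logit_scale > 0)
  structure(list(beta_scale = beta_scale, r_prior_rate = r_prior_rate,
                 pi0_logit_scale = pi0_logit_scale), class = "zc_prior")
}

#' Sampler budget and settings
#'
#' @param chains Number of MCMC chains (default 2).
#' @param draws Post-warmup draws per chain in `mcmc` mode, or total number
#'   of Gaussian draws in `approx` mode (default 1000).
#' @param warmup Warmup iterations per chain (default 500).
#' @return A `zc_sampler` list.
#' @export
sampler_config <- function(chains = 2, draws = 1000, warmup = 500) {
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup)), class = "zc_sampler")
}

## ---- internal: collapsed likelihood machinery -------------------------------

# Cells sharing (y, offset, group) contribute identical likelihood terms;
# collapsing to unique keys makes fits O(#unique) instead of O(#cells).
collapse_design <- function(y, design) {
  key <- paste(y, design$offset, as.integer(design$groups), sep = "\r")
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  list(
    y = y[first],
    offset = design$offset[first],
    gidx = as.integer(design$groups)[first],
    w = as.numeric(tabulate(idx)),
    map = idx,            # cell -> key index
    n_keys = sum(first)
  )
}

par_layout <- function(family, n_groups) {
  nm <- paste0("beta[", seq_len(n_groups), "]")
  if (has_dispersion(family)) nm <- c(nm, "log_r")
  if (has_zi(family)) nm <- c(nm, "logit_pi0")
  nm
}

# per-key log-likelihood at unconstrained theta
loglik_keys <- function(theta, family, cd, n_groups) {
  mu <- exp(cd$offset + theta[cd$gidx])
  r <- if (has_dispersion(family)) exp(theta[n_groups + 1]) else NULL
  pi0 <- if (has_zi(family)) plogis(theta[length(theta)]) else NULL
  base <- if (has_dispersion(family)) {
    dnbinom(cd$y, size = r, mu = mu, log = TRUE)
  } else {
    dpois(cd$y, lambda = mu, log = TRUE)
  }
  if (is.null(pi0)) return(base)
  out <- log1p(-pi0) + base
  z <- cd$y == 0
  if (any(z) && pi0 > 0) {
    m <- pmax(log(pi0), out[z])
    out[z] <- m + log(exp(log(pi0) - m) + exp(out[z] - m))
  }
  out
}

log_prior <- function(theta, family, n_groups, prior) {
  lp <- sum(dnorm(theta[seq_len(n_groups)], 0, prior$beta_scale, log = TRUE))
  if (has_dispersion(family)) {
    eta <- theta[n_groups + 1]             # eta = log r, 1/r ~ Exp(rate)
    lp <- lp + log(prior$r_prior_rate) - prior$r_prior_rate * exp(-eta) - eta
  }
  if (has_zi(family)) {
    lp <- lp + dnorm(theta[length(theta)], 0, prior$pi0_logit_scale, log = TRUE)
  }
  lp
}

log_post <- function(theta, family, cd, n_groups, prior) {
  ll <- sum(cd$w * loglik_keys(theta, family, cd, n_groups))
  if (!is.finite(ll)) return(-1e10)
  ll + log_prior(theta, family, n_groups, prior)
}

# vectorized over a draws x parameters matrix: per-draw, per-key log
# likelihoods (rows = draws, columns = collapsed keys)
loglik_mat <- function(theta_mat, family, cd, n_groups) {
  N <- nrow(theta_mat); K <- cd$n_keys
  mu <- exp(sweep(theta_mat[, cd$gidx, drop = FALSE], 2, cd$offset, `+`))
  Y <- matrix(cd$y, N, K, byrow = TRUE)
  base <- if (has_dispersion(family)) {
    dnbinom(Y, size = matrix(exp(theta_mat[, n_groups + 1]), N, K),
            mu = mu, log = TRUE)
  } else {
    dpois(Y, lambda = mu, log = TRUE)
  }
  if (!has_zi(family)) {
    base[!is.finite(base)] <- -1e8       # extreme proposal draws: zero weight
    return(base)
  }
  lp0 <- matrix(log(plogis(theta_mat[, ncol(theta_mat)])), N, K)
  out <- log1p(-exp(lp0)) + base
  zc <- which(cd$y == 0)
  if (length(zc)) {
    m <- pmax(lp0[, zc, drop = FALSE], out[, zc, drop = FALSE])
    out[, zc] <- m + log(exp(lp0[, zc, drop = FALSE] - m) +
                         exp(out[, zc, drop = FALSE] - m))
  }
  out[!is.finite(out)] <- -1e8
  out
}

log_post_mat <- function(theta_mat, family, cd, n_groups, prior) {
  ll <- loglik_mat(theta_mat, family, cd, n_groups) %*% cd$w
  lp <- rowSums(dnorm(theta_mat[, seq_len(n_groups), drop = FALSE],
                      0, prior$beta_scale, log = TRUE))
  if (has_dispersion(family)) {
    eta <- theta_mat[, n_groups + 1]
    lp <- lp + log(prior$r_prior_rate) - prior$r_prior_rate * exp(-eta) - eta
  }
  if (has_zi(family)) {
    lp <- lp + dnorm(theta_mat[, ncol(theta_mat)], 0,
                     prior$pi0_logit_scale, log = TRUE)
  }
  out <- drop(ll) + lp
  out[!is.finite(out)] <- -1e10
  out
}

init_theta <- function(family, y, design, cd) {
  lev <- levels(design$groups)
  expo <- exp(design$offset)
  beta <- vapply(seq_along(lev), function(g) {
    i <- as.integer(design$groups) == g
    if (!any(i)) return(0)                  # empty level (e.g. LOO refit)
    log((sum(y[i]) + 0.5) / sum(expo[i]))
  }, numeric(1))
  theta <- beta
  if (has_dispersion(family)) {
    rate <- y / expo
    m <- mean(rate); v <- var(rate)
    r0 <- if (is.finite(v) && v > m && m > 0) m^2 / (v - m) else 1
    theta <- c(theta, log(min(max(r0, 0.02), 100)))
  }
  if (has_zi(family)) theta <- c(theta, qlogis(0.1))
  names(theta) <- par_layout(family, length(lev))
  theta
}

## ---- Laplace approximation --------------------------------------------------

# analytic gradient of the log posterior; same collapsed-key layout
log_post_grad <- function(theta, family, cd, n_groups, prior) {
  mu <- exp(cd$offset + theta[cd$gidx])
  y <- cd$y; w <- cd$w
  disp <- has_dispersion(family); zi <- has_zi(family)
  if (disp) {
    r <- exp(theta[n_groups + 1])
    dmu <- y - (y + r) * mu / (r + mu)
    dr <- r * (digamma(y + r) - digamma(r) + log(r / (r + mu)) +
               1 - (y + r) / (r + mu))
  } else {
    dmu <- y - mu
    dr <- NULL
  }
  dzeta <- NULL
  if (zi) {
    zeta <- theta[length(theta)]
    pi0 <- plogis(zeta)
    z <- y == 0
    lf0 <- if (disp) r * log(r / (r + mu)) else -mu
    f0 <- exp(lf0)
    denom <- pi0 + (1 - pi0) * f0
    q <- rep(1, length(y))
    q[z] <- (1 - pi0) * f0[z] / denom[z]     # count-component responsibility
    dmu <- q * dmu
    if (disp) dr <- q * dr
    dzeta <- rep(-pi0, length(y))
    dzeta[z] <- pi0 * (1 - pi0) * (1 - f0[z]) / denom[z]
  }
  gbeta <- vapply(seq_len(n_groups), function(g) {
    i <- cd$gidx == g
    sum(w[i] * dmu[i])
  }, numeric(1))
  grad <- c(gbeta, if (disp) sum(w * dr), if (zi) sum(w * dzeta))
  # prior terms
  gp <- -theta[seq_len(n_groups)] / prior$beta_scale^2
  if (disp) gp <- c(gp, prior$r_prior_rate * exp(-theta[n_groups + 1]) - 1)
  if (zi) gp <- c(gp, -theta[length(theta)] / prior$pi0_logit_scale^2)
  grad + gp
}

laplace_fit <- function(family, cd, n_groups, prior, init) {
  negpost <- function(th) -log_post(th, family, cd, n_groups, prior)
  neggrad <- function(th) -log_post_grad(th, family, cd, n_groups, prior)
  # wide boxes keep exp()/plogis() transforms finite if a step runs away
  lo <- rep(-20, length(init)); hi <- rep(20, length(init))
  if (has_dispersion(family)) { lo[n_groups + 1] <- -12; hi[n_groups + 1] <- 15 }
  opt <- stats::optim(pmin(pmax(init, lo), hi), negpost, gr = neggrad,
                      method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500, factr = 1e4))
  # polish + Hessian at the mode
  H <- stats::optimHess(opt$par, negpost, gr = neggrad)
  ok <- opt$convergence == 0 && all(opt$par > lo + 1e-6) &&
    all(opt$par < hi - 1e-6) && all(is.finite(H))
  Sigma <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(Sigma)) {             # ridge fallback for flat directions
    H2 <- H + diag(1e-6 + abs(diag(H)) * 1e-8, nrow(H))
    Sigma <- tryCatch(chol2inv(chol(H2)), error = function(e) NULL)
    ok <- FALSE
  }
  if (is.null(Sigma)) Sigma <- diag(1e-4, length(init))
  dimnames(Sigma) <- list(names(init), names(init))
  list(mode = opt$par, Sigma = Sigma, converged = ok, lp = -opt$value)
}

safe_chol <- function(Sigma) {
  tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-8 + 1e-6 * max(diag(Sigma)), nrow(Sigma)))
  })
}

# Multivariate Student-t proposal centered at the Laplace mode. Heavier
# tails than the Gaussian keep the posterior/proposal importance ratios
# bounded for skewed posteriors (notably the zero-inflation logit).
rmvt_prop <- function(n, mean, Sigma, df = 7) {
  L <- safe_chol(Sigma)
  z <- matrix(rnorm(n * length(mean)), n)
  g <- sqrt(rchisq(n, df) / df)
  sweep((z / g) %*% L, 2, mean, `+`)
}

dmvt_log <- function(x, mean, Sigma, df = 7) {
  L <- safe_chol(Sigma)
  d <- ncol(x)
  z <- forwardsolve(t(L), t(x) - mean)
  q2 <- colSums(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - d / 2 * log(df * pi) -
    sum(log(diag(L))) - (df + d) / 2 * log1p(q2 / df)
}

## ---- adaptive Metropolis MCMC ----------------------------------------------

run_mh_chain <- function(family, cd, n_groups, prior, init, Sigma, warmup, draws) {
  d <- length(init)
  L <- tryCatch(chol((2.38^2 / d) * Sigma), error = function(e) {
    diag(0.1 / sqrt(d), d)
  })
  theta <- init
  lp <- log_post(theta, family, cd, n_groups, prior)
  scale <- 1
  out <- matrix(NA_real_, draws, d, dimnames = list(NULL, names(init)))
  lp_out <- numeric(draws)
  n_iter <- warmup + draws
  acc <- 0L
  for (i in seq_len(n_iter)) {
    prop <- theta + scale * drop(rnorm(d) %*% L)
    lp_prop <- log_post(prop, family, cd, n_groups, prior)
    a <- lp_prop - lp
    if (is.finite(a) && log(runif(1)) < a) {
      theta <- prop; lp <- lp_prop; acc <- acc + 1L
      accepted <- TRUE
    } else accepted <- FALSE
    if (i <= warmup) {          # Robbins-Monro scale adaptation toward 0.30
      scale <- scale * exp((as.numeric(accepted) - 0.30) / sqrt(i))
    } else {
      out[i - warmup, ] <- theta
      lp_out[i - warmup] <- lp
    }
  }
  list(draws = out, lp = lp_out, accept_rate = acc / n_iter)
}

split_rhat <- function(chains_mat) {
  # chains_mat: list of numeric vectors (one per chain), equal length
  halves <- unlist(lapply(chains_mat, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(chains_mat) {
  # crude initial-positive-sequence autocorrelation ESS, summed over chains
  sum(vapply(chains_mat, function(x) {
    n <- length(x)
    if (var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq_along(ac)) {
      if (ac[k] < 0.05) break
      s <- s + ac[k]
    }
    n / (1 + 2 * s)
  }, numeric(1)))
}

## ---- the public fitting interface ------------------------------------------

#' Fit one count family to a gene's UMI counts
#'
#' Bayesian fit of a single family to one gene: log link with fixed
#' sequencing-depth offset, one log-rate coefficient per covariate level,
#' and (for ZIP/ZINB) an intercept-only logistic zero-inflation component
#' shared across cells.
#'
#' Two modes are available. `"approx"` finds the posterior mode and draws
#' from the Gaussian (Laplace) approximation at the mode; each draw carries
#' an importance-weight correction `log p(theta | y) - log q(theta)` so that
#' downstream LOO computations target the true posterior. `"mcmc"` runs
#' adaptive random-walk Metropolis chains initialized at the Laplace mode
#' with proposal covariance from the Laplace curvature; convergence is
#' checked by split-chain R-hat (< 1.05 for all parameters).
#'
#' Non-convergence (including the non-identifiable case of an all-zero gene
#' under a zero-inflated family) never raises: the fit is returned with
#' `converged = FALSE` so that genes stay visible in downstream tables.
#'
#' @param y Non-negative integer counts, one per cell.
#' @param design A [design_spec()].
#' @param family One of `"P"`, `"NB"`, `"ZIP"`, `"ZINB"`.
#' @param prior A [prior_spec()].
#' @param mode `"approx"` (Laplace) or `"mcmc"`.
#' @param sampler A [sampler_config()].
#' @param seed Integer seed; all randomness in the fit derives from it.
#' @return A `zc_fit` list: `family`, `draws` (matrix draws x parameters),
#'   `lw0` (per-draw log importance correction, zero in mcmc mode),
#'   `point` (posterior-mean parameters on natural scales), `mode_par`,
#'   `converged`, `diagnostics`, `mode`, `prior`, `n_groups`,
#'   `group_levels`.
#' @export
fit_gene <- function(y, design, family, prior = prior_spec(),
                     mode = c("approx", "mcmc"), sampler = sampler_config(),
                     seed = 1L) {
  mode <- match.arg(mode)
  family <- match_family(family)
  if (length(y) != design$n_cells) stop("length(y) must equal design$n_cells")
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  # self-contained randomness: seed the fit, then restore the caller's stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  n_groups <- nlevels(design$groups)
  cd <- collapse_design(y, design)
  nonident <- all(y == 0) && has_zi(family)

  init <- init_theta(family, y, design, cd)
  lap <- laplace_fit(family, cd, n_groups, prior, init)

  if (mode == "approx") {
    S <- sampler$chains * sampler$draws
    draws <- rmvt_prop(S, lap$mode, lap$Sigma)
    colnames(draws) <- names(init)
    lp <- log_post_mat(draws, family, cd, n_groups, prior)
    lw0 <- lp - dmvt_log(draws, lap$mode, lap$Sigma)
    lw0 <- lw0 - max(lw0)
    converged <- lap$converged && !nonident
    diagnostics <- data.frame(parameter = names(init),
                              rhat = NA_real_, ess = S,
                              row.names = NULL)
  } else {
    chains <- lapply(seq_len(sampler$chains), function(k)
      run_mh_chain(family, cd, n_groups, prior,
                   init = lap$mode, Sigma = lap$Sigma,
                   warmup = sampler$warmup, draws = sampler$draws))
    draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
    lw0 <- rep(0, nrow(draws))
    per_par <- lapply(seq_along(init), function(j)
      lapply(chains, function(ch) ch$draws[, j]))
    rhat <- vapply(per_par, split_rhat, numeric(1))
    ess <- vapply(per_par, ess_basic, numeric(1))
    converged <- all(is.finite(rhat)) && all(rhat < 1.05) && !nonident
    diagnostics <- data.frame(parameter = names(init), rhat = rhat,
                              ess = ess, row.names = NULL)
  }

  fit <- structure(list(
    family = family, draws = draws, lw0 = lw0, mode_par = lap$mode,
    laplace = lap, converged = converged, nonidentifiable = nonident,
    diagnostics = diagnostics, mode = mode, prior = prior,
    sampler = sampler, seed = as.integer(seed),
    n_groups = n_groups, group_levels = levels(design$groups)
  ), class = "zc_fit")
  fit$point <- point_estimates(fit)
  fit
}

#' Posterior point estimates on natural scales
#'
#' Posterior means: group rates via `exp` per draw, shape via `exp`,
#' zero-inflation via inverse logit per draw, each averaged over draws.
#' Families without a parameter report `r = NA` / `pi0 = 0`.
#'
#' @param fit A `zc_fit`.
#' @return List with `mu_by_group` (named, UMI/10K), `r`, `pi0`.
#' @export
point_estimates <- function(fit) {
  if (is.null(fit$draws) || nrow(fit$draws) == 0) stop("fit has no draws")
  ng <- fit$n_groups
  mu <- colMeans(exp(fit$draws[, seq_len(ng), drop = FALSE]))
  names(mu) <- fit$group_levels
  r <- if (has_dispersion(fit$family)) mean(exp(fit$draws[, ng + 1])) else NA_real_
  pi0 <- if (has_zi(fit$family)) mean(plogis(fit$draws[, ncol(fit$draws)])) else 0
  list(mu_by_group = mu, r = r, pi0 = pi0)
}

#' Per-draw, per-cell log likelihoods
#'
#' Entry `(s, c)` is the log pmf of `y[c]` under posterior draw `s`. Cells
#' sharing the same (count, offset, group) are computed once internally.
#'
#' @param fit A `zc_fit`.
#' @param y The counts the fit was computed from.
#' @param design The matching [design_spec()].
#' @return Matrix, draws x cells.
#' @export
loglik_pointwise <- function(fit, y, design) {
  if (length(y) != design$n_cells) stop("length(y) must equal design$n_cells")
  if (nlevels(design$groups) != fit$n_groups) stop("design/fit group mismatch")
  cd <- collapse_design(y, design)
  llk <- loglik_mat(fit$draws, fit$family, cd, fit$n_groups)
  llk[, cd$map, drop = FALSE]
}
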