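#' Count model families
#'
#' The four count families used throughout the package, ordered by
#' complexity: Poisson (`"P"`), negative binomial (`"NB"`), zero-inflated
#' Poisson (`"ZIP"`) and zero-inflated negative binomial (`"ZINB"`).
#' The nesting partial order is P < NB, P < ZIP, NB < ZINB, ZIP < ZINB;
#' NB and ZIP are not nested in each other.
#'
#' @format Character vector of family codes.
#' @export
count_families <- c("P", "NB", "ZIP", "ZINB")

#' Complexity rank of a count family
#'
#' Number of free distributional parameters beyond the mean: P has rank 0,
#' NB and ZIP rank 1 (one extra parameter each), ZINB rank 2.
#'
#' @param family Character vector of family codes.
#' @return Integer vector of ranks.
#' @export
family_rank <- function(family) {
  family <- match_family(family)
  unname(c(P = 0L, NB = 1L, ZIP = 1L, ZINB = 2L)[family])
}

#' Strictly simpler families under the nesting partial order
#'
#' @param family A single family code.
#' @return Character vector of families that are nested special cases of
#'   `family` (transitively), excluding `family` itself.
#' @export
simpler_families <- function(family) {
  family <- match_family(family)
  switch(family,
    P    = character(0),
    NB   = "P",
    ZIP  = "P",
    ZINB = c("P", "NB", "ZIP")
  )
}

#' @rdname simpler_families
#' @export
is_zi_family <- function(family) {
  match_family(family) %in% c("ZIP", "ZINB")
}

match_family <- function(family) {
  out <- match.arg(toupper(family), count_families, several.ok = TRUE)
  if (length(out) != length(family)) stop("unknown family code")
  out
}

has_dispersion <- function(family) match_family(family) %in% c("NB", "ZINB")
has_zi <- function(family) is_zi_family(family)

check_pars <- function(family, mu, r, pi0) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive and finite")
  if (has_dispersion(family)) {
    if (is.null(r) || any(!is.finite(r)) || any(r <= 0)) {
      stop("family ", family, " requires shape r > 0")
    }
  }
  if (has_zi(family)) {
    if (is.null(pi0) || any(pi0 < 0) || any(pi0 > 1)) {
      stop("family ", family, " requires pi0 in [0, 1]")
    }
  }
  invisible(TRUE)
}

#' Log probability mass of a count family
#'
#' Evaluates the log pmf of one of the four families at counts `y`, where
#' `mu` is the per-cell mean (the gene rate in UMI per 10,000 already
#' multiplied by the cell exposure `T_c / 10^4`). The negative binomial is
#' parameterized by mean `mu` and shape `r` so that the variance is
#' `mu + mu^2 / r`. Zero-inflated families mix an obligate zero with
#' probability `pi0` into the base family; the mixture at `y = 0` is
#' evaluated by log-sum-exp so that tiny base-zero probabilities do not
#' underflow.
#'
#' @param family One of `"P"`, `"NB"`, `"ZIP"`, `"ZINB"`.
#' @param y Vector of non-negative integer counts.
#' @param mu Per-cell mean(s), recycled against `y`.
#' @param r NB shape (required for NB/ZINB).
#' @param pi0 Zero-inflation probability (required for ZIP/ZINB).
#' @return Vector of log probabilities, same length as `y`.
#' @examples
#' zi_logpmf("P", 0, mu = 1)              # -1
#' zi_logpmf("NB", 0, mu = 2, r = 2)      # 2 * log(0.5)
#' zi_logpmf("ZINB", 3, mu = 2.5, r = 1.7, pi0 = 0)  # == NB log pmf
#' @export
zi_logpmf <- function(family, y, mu, r = NULL, pi0 = NULL) {
  family <- match_family(family)
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  check_pars(family, mu, r, pi0)
  base <- switch(family,
    P    = , ZIP  = dpois(y, lambda = mu, log = TRUE),
    NB   = , ZINB = dnbinom(y, size = r, mu = mu, log = TRUE)
  )
  if (!has_zi(family)) return(base)
  # mixture: pi0 * 1{y=0} + (1 - pi0) * f(y)
  out <- log1p(-pi0) + base
  z <- y == 0
  if (any(z)) {
    lp0 <- log(pi0)
    out[z] <- if (pi0 == 0) base[z] else if (pi0 == 1) 0 else {
      bz <- out[z]
      m <- pmax(lp0, bz)
      m + log(exp(lp0 - m) + exp(bz - m))
    }
    if (pi0 == 1) out[!z] <- -Inf
  }
  out
}

#' Probability of observing a zero count
#'
#' `exp(zi_logpmf(family, 0, ...))`: non-increasing in `mu`, non-decreasing
#' in `pi0`.
#'
#' @inheritParams zi_logpmf
#' @return Probability in `[0, 1]`, vectorized over `mu`.
#' @export
prob_zero <- function(family, mu, r = NULL, pi0 = NULL) {
  exp(zi_logpmf(family, rep(0L, length(mu)), mu, r = r, pi0 = pi0))
}

#' Sample UMI counts for one gene
#'
#' Draws counts for `length(total_umi)` cells. Each cell is an obligate
#' zero with probability `pi0`; otherwise a draw from the base family with
#' mean `mu[group] * total_umi / offset_divisor`.
#'
#' @param family Family code.
#' @param mu Named (by group level) or unnamed vector of expression rates in
#'   UMI per `offset_divisor` total UMI.
#' @param total_umi Per-cell total UMI counts (sequencing depths).
#' @param groups Optional per-cell group labels matching `names(mu)`;
#'   omitted means a single shared rate.
#' @param r NB shape (NB/ZINB).
#' @param pi0 Zero-inflation probability (ZIP/ZINB); default 0.
#' @param offset_divisor Library size that defines the rate unit
#'   (default 1e4, i.e. rates are UMI/10K).
#' @return Integer vector of counts, one per cell.
#' @export
sample_counts <- function(family, mu, total_umi, groups = NULL, r = NULL,
                          pi0 = 0, offset_divisor = 1e4) {
  family <- match_family(family)
  n <- length(total_umi)
  if (is.null(groups)) {
    if (length(mu) != 1) stop("ungrouped sampling needs a single rate")
    mu_cell <- rep(mu, n)
  } else {
    if (length(groups) != n) stop("one group label per cell required")
    if (is.null(names(mu))) names(mu) <- sort(unique(as.character(groups)))
    idx <- match(as.character(groups), names(mu))
    if (anyNA(idx)) stop("unknown group label(s): ",
                         paste(unique(groups[is.na(idx)]), collapse = ", "))
    mu_cell <- mu[idx]
  }
  lambda <- mu_cell * total_umi / offset_divisor
  y <- switch(family,
    P    = , ZIP  = rpois(n, lambda),
    NB   = , ZINB = rnbinom(n, size = r, mu = lambda)
  )
  if (has_zi(family) || pi0 > 0) {
    if (pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]")
    y[runif(n) < pi0] <- 0L
  }
  as.integer(y)
}
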