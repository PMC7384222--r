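#' Compare two ELPD results
#'
#' The ELPD difference and its standard error, computed from the paired
#' per-cell log predictive densities: `diff = sum(pw_a - pw_b)` and
#' `diff_se = sd(pw_a - pw_b) * sqrt(C)`.
#'
#' @param a,b `zc_elpd` objects for the same gene, cells and cell order.
#' @return A `zc_elpd_cmp` list: `family_a`, `family_b`, `diff`, `diff_se`.
#' @export
compare_elpd <- function(a, b) {
  if (length(a$pointwise) != length(b$pointwise)) {
    stop("pointwise vectors differ in length")
  }
  d <- a$pointwise - b$pointwise
  structure(list(family_a = a$family, family_b = b$family,
                 diff = sum(d),
                 diff_se = stats::sd(d) * sqrt(length(d))),
            class = "zc_elpd_cmp")
}

#' Select a count family for one gene by the SE-multiple ladder
#'
#' Starting from the family with the highest ELPD, the call is repeatedly
#' demoted to the least-complex strictly simpler family (under the nesting
#' partial order, transitively) whose ELPD deficit is within `k` standard
#' errors of the pairwise difference — i.e. a more complex family is kept
#' only when it beats every simpler alternative by more than `k * SE`.
#' When NB and ZIP (equal complexity) are both admissible, the one with
#' higher ELPD wins, with NB preferred on an exact tie. In addition, a ZIP
#' call must hold its `k * SE` margin against NB — the preferred reference
#' model at equal complexity — not only against Poisson; without this rule
#' a non-inflated gene whose ZIP ELPD marginally exceeds NB's could never
#' be demoted. The procedure is deterministic and idempotent, and the
#' chosen complexity is non-increasing in `k`.
#'
#' @param elpds Named list of `zc_elpd` objects, one per family
#'   (names `"P"`, `"NB"`, `"ZIP"`, `"ZINB"`); families whose fit failed may
#'   be omitted or carry `converged = FALSE`.
#' @param k Non-negative SE multiple (the standard reporting thresholds
#'   are 0, 1, 2, 3).
#' @param gene_id Optional identifier carried into the result.
#' @return A `zc_selection` list: `gene_id`, `k`, `chosen` (family code or
#'   `"failed"`), `is_zi`, `elpd` (named vector), `elpd_se`.
#' @export
select_family <- function(elpds, k, gene_id = NA_character_) {
  if (k < 0) stop("k must be non-negative")
  ok <- names(elpds)[vapply(elpds, function(e)
    !is.null(e) && isTRUE(e$converged), logical(1))]
  elpd_vec <- vapply(count_families, function(f)
    if (f %in% names(elpds) && !is.null(elpds[[f]])) elpds[[f]]$elpd else NA_real_,
    numeric(1))
  se_vec <- vapply(count_families, function(f)
    if (f %in% names(elpds) && !is.null(elpds[[f]])) elpds[[f]]$se else NA_real_,
    numeric(1))
  if (length(ok) == 0) {
    return(structure(list(gene_id = gene_id, k = k, chosen = "failed",
                          is_zi = FALSE, elpd = elpd_vec, elpd_se = se_vec),
                     class = "zc_selection"))
  }
  current <- ok[which.max(elpd_vec[ok])]
  repeat {
    cand <- intersect(simpler_families(current), ok)
    # NB is the preferred reference model at complexity rank 1: a ZIP call
    # must also hold its margin against NB, not only against Poisson
    if (current == "ZIP" && "NB" %in% ok) cand <- union(cand, "NB")
    if (length(cand) == 0) break
    admissible <- cand[vapply(cand, function(m) {
      cmp <- compare_elpd(elpds[[current]], elpds[[m]])
      cmp$diff <= k * cmp$diff_se
    }, logical(1))]
    if (length(admissible) == 0) break
    rk <- family_rank(admissible)
    pool <- admissible[rk == min(rk)]
    if (length(pool) > 1) {                    # NB vs ZIP tie at rank 1
      e <- elpd_vec[pool]
      pool <- pool[e == max(e)]
      if (length(pool) > 1) pool <- intersect(c("NB", pool), pool)[1]
    }
    nxt <- pool[1]
    if (nxt == current) break
    current <- nxt
  }
  structure(list(gene_id = gene_id, k = k, chosen = current,
                 is_zi = is_zi_family(current), elpd = elpd_vec,
                 elpd_se = se_vec),
            class = "zc_selection")
}

#' Fit, score and classify every gene in a count matrix
#'
#' For each gene: fit all four families ([fit_gene()]), estimate LOO ELPD
#' for each ([elpd_loo()]), and apply the SE-multiple selection ladder at
#' each threshold in `k_list`. Non-convergent fits are kept visible with
#' their flag rather than dropped.
#'
#' @param counts Integer matrix (genes x cells, dimnames used as ids) or
#'   `Matrix::sparseMatrix`.
#' @param total_umi Per-cell total UMI used for the offset; defaults to the
#'   column sums of `counts`.
#' @param groups Optional per-cell covariate (cell type, sex, ...).
#' @param k_list SE thresholds (default `0:3`).
#' @param mode,prior,sampler,refit_policy Passed to [fit_gene()] /
#'   [elpd_loo()].
#' @param offset_divisor Rate unit (default 1e4: rates in UMI/10K).
#' @param seed Base seed; per-gene fits derive their seeds from it.
#' @param verbose Print per-gene progress.
#' @return Data frame with one row per gene x threshold: `gene_id`, `k`,
#'   ELPD and SE per family, `chosen`, `is_zi`, `converged` (all four fits
#'   converged) and `zi_score` (SE-standardized ELPD margin of the best
#'   zero-inflated family over the best non-inflated one — a continuous
#'   zero-inflation evidence score). Fitted parameters per gene and family
#'   are attached as `attr(, "params")`.
#' @export
classify_genes <- function(counts, total_umi = NULL, groups = NULL,
                           k_list = 0:3, mode = c("approx", "mcmc"),
                           prior = prior_spec(), sampler = sampler_config(),
                           refit_policy = "exact_fallback",
                           offset_divisor = 1e4, seed = 1L,
                           verbose = FALSE) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  if (any(k_list < 0)) stop("k thresholds must be non-negative")
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(total_umi)) total_umi <- colSums(counts)
  design <- design_spec(total_umi, groups = groups,
                        offset_divisor = offset_divisor)
  rows <- list()
  params <- list()
  for (g in seq_len(nrow(counts))) {
    y <- as.integer(counts[g, ])
    elpds <- list()
    for (fi in seq_along(count_families)) {
      fam <- count_families[fi]
      fit <- fit_gene(y, design, fam, prior = prior, mode = mode,
                      sampler = sampler,
                      seed = (seed + 131L * g + 17L * fi) %% 2147483629L)
      elpds[[fam]] <- elpd_loo(fit, y, design, refit_policy = refit_policy)
      pt <- fit$point
      params[[length(params) + 1L]] <- data.frame(
        gene_id = gene_ids[g], family = fam,
        group = names(pt$mu_by_group), mu = unname(pt$mu_by_group),
        r = pt$r, pi0 = pt$pi0, converged = fit$converged,
        row.names = NULL)
      if (!fit$converged && verbose) {
        message("gene ", gene_ids[g], ": ", fam, " fit did not converge")
      }
    }
    zs <- zi_score(elpds)
    for (k in k_list) {
      sel <- select_family(elpds, k, gene_id = gene_ids[g])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids[g], k = k,
        elpd_P = sel$elpd[["P"]], elpd_NB = sel$elpd[["NB"]],
        elpd_ZIP = sel$elpd[["ZIP"]], elpd_ZINB = sel$elpd[["ZINB"]],
        se_P = sel$elpd_se[["P"]], se_NB = sel$elpd_se[["NB"]],
        se_ZIP = sel$elpd_se[["ZIP"]], se_ZINB = sel$elpd_se[["ZINB"]],
        chosen = sel$chosen, is_zi = sel$is_zi,
        converged = all(vapply(elpds, function(e) e$converged, logical(1))),
        zi_score = zs, row.names = NULL)
    }
    if (verbose) message("classified gene ", g, "/", nrow(counts))
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- do.call(rbind, params)
  out
}

# SE-standardized ELPD margin of the best ZI family over the best non-ZI
# family: max over {ZIP, ZINB} of diff / diff_se against the better of
# {P, NB}. Positive values favor zero inflation.
zi_score <- function(elpds) {
  non_zi <- c("P", "NB")[which.max(c(elpds$P$elpd, elpds$NB$elpd))]
  best <- -Inf
  for (f in c("ZIP", "ZINB")) {
    if (is.null(elpds[[f]])) next
    cmp <- compare_elpd(elpds[[f]], elpds[[non_zi]])
    s <- if (cmp$diff_se > 0) cmp$diff / cmp$diff_se else sign(cmp$diff) * Inf
    if (is.nan(s)) s <- 0
    best <- max(best, s)
  }
  best
}

#' Maximum-likelihood information criteria for one gene and family
#'
#' Fits the family by (penalty-free) maximum likelihood and reports
#' `AIC = 2p - 2 logL` and `BIC = p log(C) - 2 logL`, with `p` the number
#' of free parameters (one rate per group, plus shape and/or
#' zero-inflation as applicable). A light-weight frequentist complement to
#' the LOO-based selection.
#'
#' @inheritParams fit_gene
#' @return List with `aic`, `bic`, `loglik`, `p`, `converged`.
#' @export
information_criteria <- function(y, design, family) {
  family <- match_family(family)
  if (length(y) != design$n_cells) stop("length(y) must equal design$n_cells")
  n_groups <- nlevels(design$groups)
  cd <- collapse_design(y, design)
  init <- init_theta(family, y, design, cd)
  negll <- function(th) {
    v <- -sum(cd$w * loglik_keys(th, family, cd, n_groups))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(init, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  p <- length(init)
  L <- -opt$value
  list(aic = 2 * p - 2 * L, bic = p * log(design$n_cells) - 2 * L,
       loglik = L, p = p, converged = opt$convergence == 0)
}
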