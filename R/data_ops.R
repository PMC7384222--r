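#' Filter genes by detection fraction
#'
#' Keeps genes with a nonzero UMI count in at least
#' `ceiling(min_frac * C)` cells (the default 0.10 keeps genes detected in
#' at least 10% of cells). Gene order is preserved; the operation is
#' idempotent.
#'
#' @param counts Genes x cells count matrix (dense or `Matrix` sparse).
#' @param min_frac Minimum detection fraction in `(0, 1]`.
#' @return The filtered matrix (possibly with zero rows, with a warning).
#' @export
filter_genes <- function(counts, min_frac = 0.10) {
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  n_nonzero <- Matrix::rowSums(counts > 0)
  keep <- n_nonzero >= ceiling(min_frac * ncol(counts))
  if (!any(keep)) warning("no genes pass the detection filter")
  counts[keep, , drop = FALSE]
}

#' Zero-count summaries of a count matrix
#'
#' @param counts Genes x cells count matrix.
#' @return A `zc_zeros` list: `zeros_per_cell`, `zeros_per_gene`,
#'   `depth_per_cell` (column sums). The two zero totals agree by
#'   construction.
#' @export
zero_summary <- function(counts) {
  structure(list(
    zeros_per_cell = unname(Matrix::colSums(counts == 0)),
    zeros_per_gene = unname(Matrix::rowSums(counts == 0)),
    depth_per_cell = unname(Matrix::colSums(counts))
  ), class = "zc_zeros")
}

#' Variance in zeros per cell explained by sequencing depth
#'
#' Fits a loess regression of the number of zeros per cell on the per-cell
#' total UMI count and returns `R^2 = 1 - SS_res / SS_tot`. In droplet
#' scRNA-seq data depth typically explains the large majority of the
#' variation in per-cell zero counts.
#'
#' @param zeros A [zero_summary()] result.
#' @param span,degree Loess smoothing parameters (defaults 0.75 and 2).
#' @return R-squared in `(-Inf, 1]`, or `NA` (with a warning) when the
#'   zero counts are constant.
#' @export
depth_zero_r2 <- function(zeros, span = 0.75, degree = 2) {
  z <- zeros$zeros_per_cell
  d <- zeros$depth_per_cell
  if (length(z) < 10) stop("need at least 10 cells")
  if (stats::sd(z) == 0) {
    warning("zeros per cell are constant; R^2 undefined")
    return(NA_real_)
  }
  fit <- stats::loess(z ~ d, span = span, degree = degree)
  1 - sum(stats::residuals(fit)^2) / sum((z - mean(z))^2)
}

#' Expected number of zero counts under a Poisson model
#'
#' `sum_c exp(-mu_g * T_c / divisor)`: the number of zeros a gene with
#' rate `mu_g` (UMI per `divisor` total UMI) would show under Poisson
#' sampling at the observed cell depths. Observed zeros far above this
#' expectation indicate overdispersion and/or zero inflation.
#'
#' @param mu_g Non-negative expression rate.
#' @param depths Per-cell total UMI counts.
#' @param offset_divisor Rate unit (default 1e4).
#' @return Expected zero count in `[0, C]`.
#' @export
expected_zeros_poisson <- function(mu_g, depths, offset_divisor = 1e4) {
  if (mu_g < 0) stop("mu_g must be non-negative")
  sum(exp(-mu_g * depths / offset_divisor))
}

#' Randomly permute covariate labels
#'
#' Used to test whether a drop in zero-inflation calls after adding a
#' covariate reflects real structure (shuffled labels should behave like no
#' labels) rather than a loss of power from fitting the larger model.
#'
#' @param labels Vector of labels.
#' @param seed Integer seed.
#' @return A permutation of `labels` (multiset preserved).
#' @export
shuffle_labels <- function(labels, seed = 1L) {
  set.seed(as.integer(seed))
  labels[sample.int(length(labels))]
}
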