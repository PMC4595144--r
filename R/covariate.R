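#' Estimate surrogate variables for unmodeled expression heterogeneity
#'
#' Two-step procedure: (1) per probe, regress expression on the protected
#' primary variable (case status) and form the residual matrix, so the
#' surrogate variables cannot absorb the disease signal; (2) take the top
#' right-singular vectors of that residual matrix. When `n_sv = "auto"`,
#' the number of components is chosen by parallel analysis: a component is
#' retained while its variance share exceeds the 95th percentile of the
#' corresponding component's share over matrices with every probe's
#' residuals independently permuted (20 permutations).
#'
#' @param expr probe x sample matrix (normalized log2 scale).
#' @param primary logical or two-level case labels, one per sample.
#' @param n_sv `"auto"` or a fixed number of surrogate variables.
#' @param n_perm permutations for parallel analysis (default 20).
#' @param seed seed for the permutation step.
#' @return list with `sv` (sample x n_sv orthonormal matrix) and `n_sv`.
#' @export
estimate_surrogate_variables <- function(expr, primary, n_sv = "auto",
                                         n_perm = 20, seed = 1L) {
  check_expression_matrix(expr)
  n <- ncol(expr)
  if (n < 10) stopf("need at least 10 samples for surrogate variable estimation")
  if (is.numeric(n_sv) && n_sv >= n) stopf("n_sv must be smaller than the sample count")
  design <- stats::model.matrix(~ factor(primary))
  resid <- t(stats::lm.fit(design, t(expr))$residuals) # probe x sample

  sv_full <- svd(resid, nu = 0)
  shares <- sv_full$d^2 / sum(sv_full$d^2)

  k <- if (identical(n_sv, "auto")) {
    null_shares <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- t(apply(resid, 1, sample))
        d <- svd(perm, nu = 0, nv = 0)$d
        d^2 / sum(d^2)
      }, numeric(length(shares)))
    })
    thr <- apply(null_shares, 1, stats::quantile, probs = 0.95)
    exceeds <- shares > thr
    # retain the leading run of components above the permutation threshold
    if (!exceeds[1]) 0L else which.min(c(exceeds, FALSE)) - 1L
  } else {
    as.integer(n_sv)
  }

  sv <- if (k > 0) svd(resid, nu = 0, nv = k)$v else
    matrix(numeric(0), nrow = n, ncol = 0)
  rownames(sv) <- colnames(expr)
  if (k > 0) colnames(sv) <- paste0("SV", seq_len(k))
  list(sv = sv, n_sv = k)
}

#' Residualize expression against known covariates
#'
#' Per probe, ordinary least-squares residuals against an intercept plus
#' the supplied covariate columns. Residuals are exactly orthogonal to
#' every covariate column.
#'
#' @param expr probe x sample matrix.
#' @param covariates sample x p design (data.frame or matrix); factors and
#'   logicals are expanded via [stats::model.matrix()]. `NULL` means
#'   intercept only (centering).
#' @return list with `values` (probe x sample residual matrix) and
#'   `adjusted_for` (covariate column names).
#' @export
residualize <- function(expr, covariates = NULL) {
  check_expression_matrix(expr)
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    design <- matrix(1, ncol(expr), 1, dimnames = list(colnames(expr), "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(expr))
      stopf("covariates must have one row per sample")
    design <- stats::model.matrix(~ ., data = covariates)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), qr_d$pivot[seq_len(qr_d$rank)])]
    stopf("rank-deficient covariate design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qr_d, t(expr)))
  dimnames(res) <- dimnames(expr)
  list(values = res, adjusted_for = setdiff(colnames(design), "(Intercept)"))
}
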