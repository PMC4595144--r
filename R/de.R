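#' Per-probe logistic differential expression
#'
#' For every probe, fits a logistic regression of case status on the
#' standardized probe expression plus optional covariates (surrogate
#' variables), and reports the Wald z test for the expression coefficient.
#' Probes whose fit does not converge or shows complete separation are
#' flagged and assigned p = 1.
#'
#' @param expr probe x sample matrix.
#' @param status logical case indicator (or two-level factor), per sample.
#' @param covariates optional sample x k numeric matrix (e.g. surrogate
#'   variables) entered as additional regressors.
#' @return data.frame with one row per probe: `probe_id`, `beta`
#'   (log-odds per expression SD), `se`, `p`, `p_fdr` (Benjamini-Hochberg),
#'   `converged`. The number of flagged probes is attached as attribute
#'   `n_flagged` and reported with a warning when nonzero.
#' @export
logistic_de <- function(expr, status, covariates = NULL) {
  check_expression_matrix(expr)
  y <- as.logical(status)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  if (k + 2 >= ncol(expr)) stopf("too many covariates for the sample count")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)

  fit_one <- function(x) {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
    dat <- if (is.null(covariates)) data.frame(y = y, x = x)
           else data.frame(y = y, x = x, covariates)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    # complete separation can slip past glm's own warning: flag fits whose
    # fitted probabilities have collapsed to 0/1
    if (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
      sep <- TRUE
    cf <- summary(fit)$coefficients
    ok <- fit$converged && !sep && "x" %in% rownames(cf)
    if (!ok) return(c(beta = NA_real_, se = NA_real_, p = 1, converged = 0))
    c(beta = cf["x", 1], se = cf["x", 2], p = cf["x", 4], converged = 1)
  }

  out <- t(apply(expr, 1, fit_one))
  res <- data.frame(probe_id = rownames(expr), beta = out[, "beta"],
                    se = out[, "se"], p = out[, "p"],
                    converged = out[, "converged"] == 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$p_fdr <- bh_fdr(res$p)
  n_flagged <- sum(!res$converged)
  if (n_flagged > 0)
    warning(sprintf("%d probe(s) flagged non-converged/separated (p set to 1)", n_flagged))
  attr(res, "n_flagged") <- n_flagged
  res
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values, capped at 1 and monotone after the
#' cumulative minimum from the largest rank (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-stage discovery/replication differential expression
#'
#' Selects discovery probes at `p_fdr < alpha_fdr`, refits only those in
#' the replication data, re-applies Benjamini-Hochberg within the selected
#' set, and returns the probes passing again.
#'
#' @param discovery a [logistic_de()] result on the discovery set.
#' @param replication_expr probe x sample matrix for the replication set.
#' @param status replication case labels.
#' @param covariates optional replication covariates (e.g. surrogate
#'   variables re-estimated within the replication set).
#' @param alpha_fdr FDR threshold for both stages (default 0.05).
#' @return list with `selected` (discovery probe ids taken forward),
#'   `replicated` (probe ids significant in both stages) and `replication`
#'   (the stage-two result table; `NULL` when no probe was selected).
#' @export
two_stage_replication <- function(discovery, replication_expr, status,
                                  covariates = NULL, alpha_fdr = 0.05) {
  if (alpha_fdr <= 0 || alpha_fdr > 1) stopf("alpha_fdr must be in (0, 1]")
  if (ncol(replication_expr) == 0) stopf("empty replication set")
  selected <- discovery$probe_id[discovery$p_fdr < alpha_fdr]
  if (length(selected) == 0)
    return(list(selected = character(0), replicated = character(0),
                replication = NULL))
  missing <- setdiff(selected, rownames(replication_expr))
  if (length(missing) > 0)
    stopf("selected probes absent from replication data: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  rep_de <- logistic_de(replication_expr[selected, , drop = FALSE], status, covariates)
  rep_de$p_fdr <- bh_fdr(rep_de$p)
  list(selected = selected,
       replicated = rep_de$probe_id[rep_de$p_fdr < alpha_fdr],
       replication = rep_de)
}

#' Candidate-gene lookup with Bonferroni correction
#'
#' Restricts the differential-expression table to probes mapping to a list
#' of previously implicated candidate genes and tests them at the
#' Bonferroni threshold 0.05 / (number of tested probes).
#'
#' @param de a [logistic_de()] result.
#' @param genes character vector of candidate gene symbols.
#' @param probe_to_gene data.frame with `probe_id`, `gene_symbol`.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame of `probe_id`, `gene_symbol`, `p`, `threshold`,
#'   `significant`; zero rows (with a warning) when nothing maps.
#' @export
candidate_gene_lookup <- function(de, genes, probe_to_gene, alpha = 0.05) {
  if (length(genes) == 0) stopf("candidate gene list is empty")
  if (anyDuplicated(genes)) stopf("candidate gene symbols must be unique")
  map <- probe_to_gene[probe_to_gene$gene_symbol %in% genes, , drop = FALSE]
  hits <- de[de$probe_id %in% map$probe_id, , drop = FALSE]
  if (nrow(hits) == 0) {
    warning("no probe maps to any candidate gene")
    return(data.frame(probe_id = character(0), gene_symbol = character(0),
                      p = numeric(0), threshold = numeric(0),
                      significant = logical(0)))
  }
  thr <- alpha / nrow(hits)
  data.frame(
    probe_id = hits$probe_id,
    gene_symbol = map$gene_symbol[match(hits$probe_id, map$probe_id)],
    p = hits$p, threshold = thr, significant = hits$p < thr,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
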