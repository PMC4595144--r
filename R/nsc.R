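# Nearest shrunken centroid (PAM-style) two-class disease classifier.

#' Fit a nearest shrunken centroid classifier
#'
#' Per gene i and class k, the standardized centroid difference is
#' `d_ik = (class mean - overall mean) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, pooled within-class standard deviation `s_i`
#' and fudge constant `s0 = median(s_i)`. Soft-thresholding
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)` shrinks uninformative
#' genes to the overall centroid; the shrunken class centroid is
#' `overall mean + m_k * (s_i + s0) * d'_ik`. A gene is active at a given
#' `delta` when `d'_ik` is nonzero for some class.
#'
#' @param expr gene x sample matrix.
#' @param status logical case indicator per sample (`TRUE` = case).
#' @param delta_grid shrinkage thresholds; default 30 linear values from 0
#'   to `max |d_ik|`.
#' @param priors class prior probabilities `c(control, case)`; default the
#'   observed class frequencies.
#' @return an object of class `"nsc"`: overall centroid, per-class
#'   standardized differences, pooled SDs, `s0`, priors, the delta grid
#'   and (until [nsc_cv()] is run) `chosen_delta = 0`.
#' @seealso [nsc_cv()], [predict.nsc()], [smallest_gene_set_report()]
#' @export
fit_nsc <- function(expr, status, delta_grid = NULL, priors = NULL) {
  check_expression_matrix(expr)
  y <- as.logical(status)
  n_k <- c(control = sum(!y), case = sum(y))
  if (any(n_k < 3)) stopf("each class needs at least 3 samples")
  n <- sum(n_k)

  overall <- rowMeans(expr)
  cls_means <- cbind(control = rowMeans(expr[, !y, drop = FALSE]),
                     case = rowMeans(expr[, y, drop = FALSE]))
  ss <- (expr[, !y, drop = FALSE] - cls_means[, "control"])^2
  ss2 <- (expr[, y, drop = FALSE] - cls_means[, "case"])^2
  pooled_sd <- sqrt((rowSums(ss) + rowSums(ss2)) / (n - 2))
  if (all(pooled_sd == 0)) stopf("degenerate data: all pooled SDs are zero")
  s0 <- stats::median(pooled_sd)
  m_k <- sqrt(1 / n_k - 1 / n)
  d_ik <- sweep(cls_means - overall, 2, m_k, "/") / (pooled_sd + s0)

  if (is.null(delta_grid)) delta_grid <- seq(0, max(abs(d_ik)), length.out = 30)
  if (is.null(priors)) priors <- n_k / n else {
    priors <- stats::setNames(priors, c("control", "case"))
    if (abs(sum(priors) - 1) > 1e-8) stopf("priors must sum to 1")
  }

  structure(list(
    overall_centroid = overall, class_means = cls_means, d_ik = d_ik,
    pooled_sd = pooled_sd, s0 = s0, m_k = m_k, priors = priors,
    n_k = n_k, delta_grid = delta_grid, chosen_delta = 0,
    cv_errors = NULL, genes = rownames(expr)
  ), class = "nsc")
}

# soft-thresholded standardized differences at a given delta
shrink_d <- function(object, delta) {
  sign(object$d_ik) * pmax(abs(object$d_ik) - delta, 0)
}

#' Shrunken class centroids of a fitted classifier
#'
#' @param object an `"nsc"` model.
#' @param delta shrinkage threshold (default the model's chosen delta).
#' @return gene x class matrix of shrunken centroids.
#' @export
shrunken_centroids <- function(object, delta = object$chosen_delta) {
  dprime <- shrink_d(object, delta)
  object$overall_centroid +
    sweep(dprime, 2, object$m_k, "*") * (object$pooled_sd + object$s0)
}

#' Genes with a nonzero shrunken difference at a given delta
#'
#' @inheritParams shrunken_centroids
#' @return character vector of active gene ids.
#' @export
active_genes <- function(object, delta = object$chosen_delta) {
  object$genes[rowSums(abs(shrink_d(object, delta)) > 0) > 0]
}

#' Cross-validate the shrinkage threshold
#'
#' Stratified k-fold cross-validation of the misclassification rate over
#' the model's delta grid. The chosen delta is the largest value whose
#' cross-validated error equals the minimum (preferring smaller gene sets
#' at equal error). Folds containing a single class trigger a refold with
#' a new derived seed, at most 10 times.
#'
#' @param expr gene x sample matrix (the data the model was fitted to).
#' @param status logical case labels.
#' @param delta_grid thresholds to evaluate; default the fitted grid.
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param object optionally, an existing [fit_nsc()] model whose grid and
#'   priors are reused.
#' @return the fitted `"nsc"` model with `cv_errors` (per-delta mean fold
#'   misclassification) and `chosen_delta` filled in.
#' @export
nsc_cv <- function(expr, status, delta_grid = NULL, n_folds = 10, seed = 1L,
                   object = NULL) {
  if (n_folds < 2) stopf("n_folds must be >= 2")
  y <- as.logical(status)
  if (is.null(object)) object <- fit_nsc(expr, y, delta_grid = delta_grid)
  grid <- object$delta_grid

  make_folds <- function(s) with_seed(s, {
    fold <- integer(length(y))
    for (grp in c(TRUE, FALSE)) {
      idx <- sample(which(y == grp))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
  fold <- NULL
  for (attempt in seq_len(10)) {
    cand <- make_folds(seed + attempt - 1L)
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[cand != f])) == 2, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold)) stopf("could not build folds with both classes in every training set")

  err <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    train <- fold != f
    fit_f <- fit_nsc(expr[, train, drop = FALSE], y[train], delta_grid = grid,
                     priors = object$priors)
    for (j in seq_along(grid)) {
      pred <- predict(fit_f, expr[, !train, drop = FALSE], delta = grid[j])
      err[f, j] <- mean((pred$class == "case") != y[!train])
    }
  }
  cv_errors <- colMeans(err)
  best <- min(cv_errors)
  object$cv_errors <- cv_errors
  object$chosen_delta <- max(grid[cv_errors == best])
  object
}

#' Predict class membership with a shrunken-centroid model
#'
#' The discriminant for class k is
#' `delta_k(x) = sum_i (x_i - centroid_ik)^2 / (s_i + s0)^2 - 2 log(prior_k)`
#' over the active genes; the predicted class minimizes it (ties predict
#' control) and class probabilities are proportional to
#' `exp(-delta_k / 2)`.
#'
#' @param object an `"nsc"` model.
#' @param newdata gene x sample matrix containing the model's genes.
#' @param delta shrinkage threshold (default the model's chosen delta).
#' @param status optional true case labels; when given, misclassification
#'   rate, sensitivity and specificity are attached.
#' @param ... unused.
#' @return an `"nsc_prediction"` list: `table` (per-sample `prob_control`,
#'   `prob_case`, `class`), `n_active`, and — when `status` is supplied —
#'   `misclassification`, `sensitivity`, `specificity`.
#' @export
predict.nsc <- function(object, newdata, delta = object$chosen_delta,
                        status = NULL, ...) {
  missing <- setdiff(object$genes, rownames(newdata))
  if (length(missing) > 0)
    stopf("genes absent from new data: %s%s",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  act <- active_genes(object, delta)
  cent <- shrunken_centroids(object, delta)
  disc <- matrix(0, ncol(newdata), 2, dimnames = list(colnames(newdata),
                                                      c("control", "case")))
  if (length(act) > 0) {
    xs <- newdata[act, , drop = FALSE]
    w <- (object$pooled_sd[act] + object$s0)^2
    for (k in c("control", "case"))
      disc[, k] <- colSums((xs - cent[act, k])^2 / w)
  }
  disc <- sweep(disc, 2, 2 * log(object$priors), "-")
  # ties go to control: case wins only on strictly smaller discriminant
  cls <- ifelse(disc[, "case"] < disc[, "control"], "case", "control")
  rel <- exp(-(disc - apply(disc, 1, min)) / 2)
  probs <- rel / rowSums(rel)
  tab <- data.frame(sample_id = colnames(newdata),
                    prob_control = probs[, "control"],
                    prob_case = probs[, "case"],
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  out <- list(table = tab, n_active = length(act), delta = delta,
              class = cls)
  if (!is.null(status)) {
    y <- as.logical(status)
    pred_case <- cls == "case"
    out$misclassification <- mean(pred_case != y)
    out$sensitivity <- if (any(y)) mean(pred_case[y]) else NA_real_
    out$specificity <- if (any(!y)) mean(!pred_case[!y]) else NA_real_
  }
  class(out) <- "nsc_prediction"
  out
}

#' @export
print.nsc <- function(x, ...) {
  cat(sprintf("Nearest shrunken centroid classifier: %d genes, n = %d (%d cases, %d controls)\n",
              length(x$genes), sum(x$n_k), x$n_k[["case"]], x$n_k[["control"]]))
  cat(sprintf("  s0 = %.4g; delta grid: %d values in [0, %.3g]\n",
              x$s0, length(x$delta_grid), max(x$delta_grid)))
  if (!is.null(x$cv_errors))
    cat(sprintf("  chosen delta %.3g (CV error %.3f, %d active genes)\n",
                x$chosen_delta, min(x$cv_errors),
                length(active_genes(x, x$chosen_delta))))
  invisible(x)
}

#' @export
summary.nsc <- function(object, ...) {
  n_active <- vapply(object$delta_grid, function(d)
    length(active_genes(object, d)), integer(1))
  out <- data.frame(delta = object$delta_grid, n_active = n_active)
  if (!is.null(object$cv_errors)) out$cv_error <- object$cv_errors
  out
}

#' @export
print.nsc_prediction <- function(x, ...) {
  cat(sprintf("NSC prediction: %d samples, %d active genes (delta %.3g)\n",
              nrow(x$table), x$n_active, x$delta))
  if (!is.null(x$misclassification))
    cat(sprintf("  misclassification %.3f, sensitivity %.3f, specificity %.3f\n",
                x$misclassification, x$sensitivity, x$specificity))
  invisible(x)
}

#' Plot the cross-validation curve of a shrunken-centroid model
#'
#' @param x a cross-validated `"nsc"` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nsc <- function(x, ...) {
  if (is.null(x$cv_errors)) stopf("run nsc_cv() first")
  graphics::plot(x$delta_grid, x$cv_errors, type = "b", xlab = "shrinkage delta",
                 ylab = "CV misclassification", ...)
  graphics::abline(v = x$chosen_delta, lty = 2)
  invisible(x)
}

#' Smallest gene set meeting a misclassification ceiling
#'
#' Scans the delta grid from most to least shrunken and returns the first
#' (hence smallest) nonempty active gene set whose misclassification on
#' the evaluation data is at or below `error_ceiling`.
#'
#' @param object an `"nsc"` model.
#' @param expr_new gene x sample evaluation matrix (e.g. replication set).
#' @param status_new true case labels for the evaluation samples.
#' @param error_ceiling acceptable misclassification rate in `(0, 1)`.
#' @return list with `qualified` (logical), `genes`, `delta`,
#'   `misclassification`, `sensitivity`, `specificity`; when no delta
#'   qualifies, `qualified = FALSE` with the best achieved error and an
#'   empty gene set.
#' @export
smallest_gene_set_report <- function(object, expr_new, status_new, error_ceiling) {
  if (error_ceiling <= 0 || error_ceiling > 1) stopf("error_ceiling must be in (0, 1]")
  grid <- sort(object$delta_grid, decreasing = TRUE)
  best <- NULL
  for (d in grid) {
    act <- active_genes(object, d)
    if (length(act) == 0) next
    pred <- predict(object, expr_new, delta = d, status = status_new)
    rec <- list(qualified = pred$misclassification <= error_ceiling,
                genes = act, delta = d,
                misclassification = pred$misclassification,
                sensitivity = pred$sensitivity, specificity = pred$specificity)
    if (rec$qualified) return(rec)
    if (is.null(best) || rec$misclassification < best$misclassification) best <- rec
  }
  if (is.null(best)) stopf("no delta in the grid yields a nonempty gene set")
  best$qualified <- FALSE
  best$genes <- character(0)
  best
}
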