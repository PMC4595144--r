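#' Exclude samples failing laboratory quality thresholds
#'
#' Flags samples with an RNA integrity number strictly below `rin_min`
#' (reason `low_rin`) or a 260/280 absorbance ratio strictly below
#' `purity_min` (reason `low_purity`). A sample failing both is reported
#' once, as `low_rin`.
#'
#' @param metadata sample metadata with `rin` and `ratio_260_280` columns.
#' @param rin_min RIN threshold (default 6).
#' @param purity_min 260/280 threshold (default 1.8).
#' @return data.frame of `sample_id`, `reason`.
#' @export
filter_lab_quality <- function(metadata, rin_min = 6, purity_min = 1.8) {
  if (rin_min <= 0 || purity_min <= 0) stopf("thresholds must be positive")
  bad <- is.na(metadata$rin) | is.na(metadata$ratio_260_280)
  if (any(bad))
    stopf("missing RIN or 260/280 ratio for sample(s): %s",
          paste(metadata$sample_id[bad], collapse = ", "))
  reason <- ifelse(metadata$rin < rin_min, "low_rin",
                   ifelse(metadata$ratio_260_280 < purity_min, "low_purity", NA))
  out <- data.frame(sample_id = metadata$sample_id, reason = reason,
                    stringsAsFactors = FALSE)
  out[!is.na(out$reason), , drop = FALSE]
}

#' Flag principal-component outlier samples
#'
#' Computes the first two principal components of the centered sample x
#' probe matrix via singular value decomposition and flags samples whose
#' PC1 or PC2 score deviates from the component median by more than
#' `k_mad` robust standard deviations. The robust SD is the larger of the
#' scaled median absolute deviation and a decile-range estimate
#' (`(q90 - q10) / 2.563`); the decile guard keeps legitimate multimodal
#' structure (chip-batch clusters on a PC) from collapsing the spread
#' estimate and mass-flagging whole batches, while a few gross outliers
#' still stand out against either estimate.
#'
#' @param expr probe x sample expression matrix.
#' @param k_mad robust-SD multiplier (default 5).
#' @return data.frame of `sample_id`, `reason` (`pc_outlier`), `pc1`, `pc2`.
#' @export
detect_pc_outliers <- function(expr, k_mad = 5) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3) stopf("need at least 3 samples for PC outlier detection")
  if (k_mad <= 0) stopf("k_mad must be positive")
  centered <- expr - rowMeans(expr)
  if (all(centered == 0)) stopf("constant expression matrix: no variance to decompose")
  sv <- svd(t(centered), nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], 2)
  flagged <- rep(FALSE, ncol(expr))
  for (k in 1:2) {
    s <- scores[, k]
    # mad constant 1.4826 and decile divisor 2*qnorm(0.9): both estimate
    # the SD under normality; the decile range survives batch multimodality
    spread <- max(stats::mad(s),
                  diff(stats::quantile(s, c(0.1, 0.9), names = FALSE)) /
                    (2 * stats::qnorm(0.9)))
    if (spread == 0) spread <- stats::sd(s)
    if (spread > 0) flagged <- flagged | abs(s - stats::median(s)) > k_mad * spread
  }
  data.frame(sample_id = colnames(expr)[flagged],
             reason = rep("pc_outlier", sum(flagged)),
             pc1 = scores[flagged, 1], pc2 = scores[flagged, 2],
             stringsAsFactors = FALSE)
}

# exact 1-D two-means split: returns threshold at the midpoint of the two
# cluster means of the best (minimum within-SS) split of sorted values
two_means_threshold <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  best <- Inf; best_k <- 1
  for (k in seq_len(n - 1)) {
    m1 <- cs[k] / k
    m2 <- (cs[n] - cs[k]) / (n - k)
    ss <- (cs2[k] - k * m1^2) + ((cs2[n] - cs2[k]) - (n - k) * m2^2)
    if (ss < best) { best <- ss; best_k <- k }
  }
  m1 <- cs[best_k] / best_k
  m2 <- (cs[n] - cs[best_k]) / (n - best_k)
  (m1 + m2) / 2
}

#' Check concordance between reported sex and sex-chromosome expression
#'
#' Each sex-check probe partitions the samples by a two-cluster
#' one-dimensional split (threshold at the midpoint of the two cluster
#' means); the side agreeing with the majority of reported sexes defines
#' the probe's predicted sex. Samples for which at least `min_discordant`
#' probes predict the opposite of the reported sex are excluded.
#'
#' @param expr probe x sample matrix (must contain the sex-check probes).
#' @param annotation probe annotation with `is_sex_check_probe`.
#' @param metadata sample metadata with `reported_sex` in `{M, F}`.
#' @param min_discordant probes needed to call a mismatch (default 2).
#' @return data.frame of `sample_id`, `reason` (`sex_mismatch`),
#'   `n_discordant`.
#' @export
check_sex_concordance <- function(expr, annotation, metadata, min_discordant = 2) {
  sex_probes <- annotation$probe_id[annotation$is_sex_check_probe]
  sex_probes <- intersect(sex_probes, rownames(expr))
  if (length(sex_probes) < min_discordant)
    stopf("need at least %d sex-check probes, found %d", min_discordant, length(sex_probes))
  reported <- metadata$reported_sex[match(colnames(expr), metadata$sample_id)]
  is_m <- reported == "M"
  discord <- rep(0L, ncol(expr))
  for (pr in sex_probes) {
    v <- expr[pr, ]
    thr <- two_means_threshold(v)
    high <- v > thr
    # orient by majority agreement with reported sex
    pred_m <- if (mean(high == is_m) >= 0.5) high else !high
    discord <- discord + as.integer(pred_m != is_m)
  }
  keep <- discord >= min_discordant
  data.frame(sample_id = colnames(expr)[keep],
             reason = rep("sex_mismatch", sum(keep)),
             n_discordant = discord[keep], stringsAsFactors = FALSE)
}

#' Detect duplicate samples by inter-sample Pearson correlation
#'
#' For every sample pair with correlation above `r_min`, the later sample
#' in column order is excluded; transitive groups of near-copies keep
#' exactly one (the earliest) representative.
#'
#' @param expr probe x sample matrix.
#' @param r_min correlation threshold in (0, 1), default 0.99.
#' @return data.frame of `sample_id`, `reason` (`duplicate`),
#'   `duplicate_of`.
#' @export
detect_duplicates <- function(expr, r_min = 0.99) {
  check_expression_matrix(expr)
  if (r_min <= 0 || r_min >= 1) stopf("r_min must be in (0,1)")
  cc <- stats::cor(expr)
  excluded <- character(0); kept_of <- character(0)
  alive <- rep(TRUE, ncol(expr))
  for (j in seq_len(ncol(expr))) {
    if (!alive[j]) next
    hits <- which(cc[j, ] > r_min & seq_len(ncol(cc)) > j & alive)
    if (length(hits) > 0) {
      excluded <- c(excluded, colnames(expr)[hits])
      kept_of <- c(kept_of, rep(colnames(expr)[j], length(hits)))
      alive[hits] <- FALSE
    }
  }
  data.frame(sample_id = excluded, reason = rep("duplicate", length(excluded)),
             duplicate_of = kept_of, stringsAsFactors = FALSE)
}

#' Filter probes on specificity, chromosome and retirement status
#'
#' Excludes non-specific probes (reason `nonspecific`), probes on
#' chromosomes X, Y or MT (reason `non_autosomal`) and probes mapping to
#' retired transcripts (reason `retired`). A probe matching several rules
#' is reported under the first matching reason in that order.
#'
#' @param annotation probe annotation table.
#' @return data.frame of `probe_id`, `reason`.
#' @export
filter_probes <- function(annotation) {
  chr <- toupper(as.character(annotation$chromosome))
  known <- c(as.character(1:22), "X", "Y", "MT")
  if (!all(chr %in% known))
    stopf("unknown chromosome label(s): %s",
          paste(unique(chr[!chr %in% known]), collapse = ", "))
  reason <- ifelse(!annotation$is_specific, "nonspecific",
                   ifelse(chr %in% c("X", "Y", "MT"), "non_autosomal",
                          ifelse(annotation$is_retired, "retired", NA)))
  out <- data.frame(probe_id = annotation$probe_id, reason = reason,
                    stringsAsFactors = FALSE)
  out[!is.na(out$reason), , drop = FALSE]
}

#' Quantile normalize raw intensities and log2 transform
#'
#' After normalization every sample column carries the identical sorted
#' value vector (the per-rank mean across samples); log2 is then applied.
#' Normalization is delegated to [limma::normalizeQuantiles()].
#'
#' @param expr probe x sample matrix of strictly positive raw intensities.
#' @return normalized, log2-transformed matrix with dimnames preserved.
#' @export
quantile_normalize_log2 <- function(expr) {
  check_expression_matrix(expr)
  if (any(expr <= 0)) stopf("raw intensities must be strictly positive before log2")
  qn <- limma::normalizeQuantiles(expr)
  dimnames(qn) <- dimnames(expr)
  log2(qn)
}

#' Split samples into discovery and replication sets
#'
#' Within each stratum (cases, controls) assigns 2/3 of samples to the
#' discovery set and 1/3 to replication (replication size is the floor,
#' remainder to discovery), at random under `seed`.
#'
#' @param metadata sample metadata with `is_case`.
#' @param seed integer seed.
#' @return data.frame of `sample_id`, `set_label`.
#' @export
split_discovery_replication <- function(metadata, seed = 1L) {
  for (grp in c(TRUE, FALSE)) {
    if (sum(metadata$is_case == grp) < 3)
      stopf("stratum '%s' has fewer than 3 samples", if (grp) "case" else "control")
  }
  lab <- with_seed(seed, suggest_split(metadata$is_case))
  data.frame(sample_id = metadata$sample_id, set_label = lab,
             stringsAsFactors = FALSE)
}

#' Compare leukocyte differential counts between cases and controls
#'
#' Runs a two-sample Wilcoxon rank-sum test per leukocyte type
#' (tie-corrected normal approximation with continuity correction) and
#' reports the case-group rank sum and the two-sided p-value.
#'
#' @param metadata sample metadata with `is_case` and `leuko_*` columns.
#' @return data.frame of `cell_type`, `rank_sum` (cases), `p`.
#' @export
compare_leukocyte_counts <- function(metadata) {
  cols <- grep("^leuko_", names(metadata), value = TRUE)
  if (length(cols) == 0) stopf("no leukocyte count columns (leuko_*) in metadata")
  res <- lapply(cols, function(cl) {
    x <- metadata[[cl]][metadata$is_case]
    y <- metadata[[cl]][!metadata$is_case]
    if (length(x) < 2 || length(y) < 2)
      stopf("leukocyte comparison needs >= 2 observations per group (%s)", cl)
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    data.frame(cell_type = sub("^leuko_", "", cl),
               rank_sum = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full sample and probe quality-control pipeline
#'
#' Applies, in order: lab-quality filters, principal-component outlier
#' detection, sex-concordance check, duplicate detection (samples); then
#' probe filters; then quantile normalization and log2 transformation.
#' Each later sample step operates on the samples surviving the earlier
#' ones.
#'
#' @param expr raw probe x sample intensity matrix.
#' @param metadata sample metadata table.
#' @param annotation probe annotation table.
#' @param rin_min,purity_min,k_mad,min_discordant,r_min stage thresholds.
#' @return a `qc_result` list: `expression` (normalized log2 matrix of the
#'   retained probes x samples), `report` (a `qc_report` with exclusion
#'   tables and retained counts), plus the filtered `metadata` and
#'   `annotation`.
#' @export
run_qc <- function(expr, metadata, annotation, rin_min = 6, purity_min = 1.8,
                   k_mad = 5, min_discordant = 2, r_min = 0.99) {
  check_expression_matrix(expr)
  if (!identical(colnames(expr), metadata$sample_id))
    stopf("expression columns and metadata rows must match one-to-one")
  if (!identical(rownames(expr), annotation$probe_id))
    stopf("expression rows and annotation rows must match one-to-one")

  if (any(expr <= 0)) stopf("raw intensities must be strictly positive")
  qc_mat <- log2(expr) # sample QC on the log scale; re-normalized afterwards
  keep <- colnames(expr)

  lab <- filter_lab_quality(metadata[metadata$sample_id %in% keep, ], rin_min, purity_min)
  keep <- setdiff(keep, lab$sample_id)

  pc <- detect_pc_outliers(qc_mat[, keep, drop = FALSE], k_mad)
  keep <- setdiff(keep, pc$sample_id)

  # data already stripped of sex probes (e.g. a QC rerun) skip the sex check
  n_sex <- sum(annotation$is_sex_check_probe %in% TRUE &
                 annotation$probe_id %in% rownames(expr))
  sx <- if (n_sex >= min_discordant) {
    check_sex_concordance(qc_mat[, keep, drop = FALSE], annotation,
                          metadata, min_discordant)
  } else {
    data.frame(sample_id = character(0), reason = character(0),
               n_discordant = integer(0), stringsAsFactors = FALSE)
  }
  keep <- setdiff(keep, sx$sample_id)

  dup <- detect_duplicates(qc_mat[, keep, drop = FALSE], r_min)
  keep <- setdiff(keep, dup$sample_id)

  excluded_samples <- data.frame(
    sample_id = c(lab$sample_id, pc$sample_id, sx$sample_id, dup$sample_id),
    reason = c(lab$reason, pc$reason, sx$reason, dup$reason),
    stringsAsFactors = FALSE
  )

  excluded_probes <- filter_probes(annotation)
  keep_probes <- setdiff(rownames(expr), excluded_probes$probe_id)

  normalized <- quantile_normalize_log2(expr[keep_probes, keep, drop = FALSE])

  report <- structure(list(
    excluded_samples = excluded_samples,
    excluded_probes = excluded_probes,
    n_samples_retained = length(keep),
    n_probes_retained = length(keep_probes),
    n_samples_input = ncol(expr),
    n_probes_input = nrow(expr)
  ), class = "qc_report")

  list(
    expression = normalized,
    metadata = metadata[metadata$sample_id %in% keep, , drop = FALSE],
    annotation = annotation[annotation$probe_id %in% keep_probes, , drop = FALSE],
    report = report
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d samples and %d/%d probes retained\n",
              x$n_samples_retained, x$n_samples_input,
              x$n_probes_retained, x$n_probes_input))
  if (nrow(x$excluded_samples) > 0) {
    tab <- table(x$excluded_samples$reason)
    cat("  sample exclusions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (nrow(x$excluded_probes) > 0) {
    tab <- table(x$excluded_probes$reason)
    cat("  probe exclusions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
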