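# Differential co-expression: group-wise signed-powered correlation
# difference, module extraction, dispersion statistic with label-permutation
# inference, and Z-summary module preservation.

signed_power_cor <- function(expr, beta) {
  rho <- spearman_cor(t(expr))
  sign(rho) * abs(rho)^beta
}

#' Differential co-expression dissimilarity between two groups
#'
#' With signed-powered Spearman correlations `c_g = sign(rho) * |rho|^beta`
#' computed separately in cases and controls, the change score is
#' `d_ij = sqrt(0.5 * |c_case,ij - c_control,ij|)`, bounded in `[0, 1]`
#' with zero diagonal. Large `d` means a large case-control change in
#' co-expression.
#'
#' @param expr_cases,expr_controls probe x sample matrices over the same
#'   gene set.
#' @param beta soft-threshold power (default 6).
#' @return gene x gene change matrix `d`.
#' @export
dc_dissimilarity <- function(expr_cases, expr_controls, beta = 6) {
  if (!identical(rownames(expr_cases), rownames(expr_controls)))
    stopf("case and control matrices must share the same gene set")
  if (ncol(expr_cases) < 3 || ncol(expr_controls) < 3)
    stopf("need at least 3 samples per group")
  d <- sqrt(0.5 * abs(signed_power_cor(expr_cases, beta) -
                        signed_power_cor(expr_controls, beta)))
  diag(d) <- 0
  attr(d, "beta") <- beta
  d
}

#' Extract differentially co-expressed modules
#'
#' Average-linkage clustering of the change matrix `d` under dissimilarity
#' `1 - d` (genes whose co-expression changes together cluster together),
#' with the same static-cut machinery as [extract_modules()]. Following
#' the random colour-labelling convention for differential-co-expression
#' modules, colours are assigned in seeded random order.
#'
#' @param d change matrix from [dc_dissimilarity()].
#' @param cut_height static cut height (default 0.96).
#' @param min_module_size smallest reportable module (default 30).
#' @param seed seed for the colour labels.
#' @return a `module_assignment` data.frame.
#' @export
extract_dc_modules <- function(d, cut_height = 0.96, min_module_size = 30, seed = 1L) {
  extract_modules(d, cut_height = cut_height, min_module_size = min_module_size,
                  shuffle_colors = TRUE, seed = seed)
}

#' Dispersion statistic of a gene module
#'
#' Root-mean-square of the pairwise change scores over the unordered
#' within-module pairs: `D_s = sqrt(mean_{i<j} d_ij^2)`.
#'
#' @param d change matrix from [dc_dissimilarity()].
#' @param module character vector of member genes (>= 2).
#' @return scalar dispersion statistic in `[0, 1]`.
#' @export
dispersion_statistic <- function(d, module) {
  idx <- match(module, rownames(d))
  if (anyNA(idx)) stopf("module gene(s) absent from the change matrix")
  if (length(idx) < 2) stopf("dispersion statistic needs a module of >= 2 genes")
  sub <- d[idx, idx]
  sqrt(mean(sub[upper.tri(sub)]^2))
}

#' Permutation test for differential co-expression of modules
#'
#' Keeps module membership fixed and permutes case/control labels
#' (preserving group sizes); each permutation recomputes the change matrix
#' restricted to each module and its dispersion statistic. The
#' permutation index is the count of null statistics at or above the
#' observed one; `p_emp = perm_index / n_perm` and
#' `p_bonf = min(1, m * p_emp)` with `m` the number of modules tested.
#' `exhaustive = TRUE` enumerates all distinct label splits instead of
#' sampling (only sensible for very small groups).
#'
#' @param expr_cases,expr_controls probe x sample matrices (same genes).
#' @param modules a module assignment (`"unassigned"` is ignored).
#' @param n_perm number of permutations (>= 100, default 10000).
#' @param beta soft-threshold power (default 6).
#' @param seed permutation seed.
#' @param exhaustive enumerate all label splits (caps at choose(n, n_cases)).
#' @return a `dispersion_result` data.frame per module: `module`,
#'   `n_genes`, `d_s`, `perm_index`, `p_emp`, `p_bonf`, `n_perm`.
#' @export
dc_permutation_test <- function(expr_cases, expr_controls, modules,
                                n_perm = 10000, beta = 6, seed = 1L,
                                exhaustive = FALSE) {
  if (!exhaustive && n_perm < 100) stopf("n_perm must be >= 100 for a stable null")
  mods <- setdiff(unique(modules$module), "unassigned")
  if (length(mods) == 0)
    return(structure(data.frame(module = character(0), n_genes = integer(0),
                                d_s = numeric(0), perm_index = integer(0),
                                p_emp = numeric(0), p_bonf = numeric(0),
                                n_perm = integer(0)),
                     class = c("dispersion_result", "data.frame")))
  pooled <- cbind(expr_cases, expr_controls)
  n1 <- ncol(expr_cases); n <- ncol(pooled)
  member_idx <- lapply(mods, function(m)
    match(modules$gene[modules$module == m], rownames(pooled)))

  mod_ds <- function(case_cols) {
    ctrl_cols <- setdiff(seq_len(n), case_cols)
    vapply(member_idx, function(idx) {
      sub_d <- sqrt(0.5 * abs(
        signed_power_cor(pooled[idx, case_cols, drop = FALSE], beta) -
          signed_power_cor(pooled[idx, ctrl_cols, drop = FALSE], beta)))
      diag(sub_d) <- 0
      sqrt(mean(sub_d[upper.tri(sub_d)]^2))
    }, numeric(1))
  }

  observed <- mod_ds(seq_len(n1))
  null_mat <- if (exhaustive) {
    splits <- utils::combn(n, n1)
    n_perm <- ncol(splits)
    vapply(seq_len(n_perm), function(i) mod_ds(splits[, i]), numeric(length(mods)))
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(i)
      mod_ds(sample.int(n, n1)), numeric(length(mods))))
  }
  null_mat <- matrix(null_mat, nrow = length(mods))
  perm_index <- rowSums(null_mat >= observed)
  p_emp <- perm_index / n_perm
  out <- data.frame(
    module = mods,
    n_genes = lengths(member_idx),
    d_s = observed,
    perm_index = as.integer(perm_index),
    p_emp = p_emp,
    p_bonf = bonferroni_from_index(perm_index, n_perm, length(mods)),
    n_perm = as.integer(n_perm),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dispersion_result", "data.frame")
  out
}

#' Convert a permutation index to a Bonferroni-corrected p-value
#'
#' `p_bonf = min(1, m * perm_index / n_perm)`, the correction applied to
#' the empirical permutation p-value when `m` modules are tested.
#'
#' @param perm_index count of null statistics at or above the observed.
#' @param n_perm number of permutations.
#' @param m number of modules tested.
#' @return Bonferroni-corrected empirical p-value(s).
#' @export
bonferroni_from_index <- function(perm_index, n_perm, m) {
  p <- m * perm_index / n_perm
  p[p > 1] <- 1
  p
}

#' Z-summary module preservation between discovery and replication
#'
#' Density statistic: mean within-module edge weight of the module's
#' network computed in the replication data. Connectivity statistic:
#' correlation between the genes' intramodular connectivity (within-module
#' row sums) in discovery vs replication. Each is standardized against a
#' null of `n_perm` random same-size gene sets drawn in the replication
#' data: `Z = (observed - mean_null) / sd_null`. The Z-summary is the mean
#' of the two Z scores; a module is preserved when `z_summary > 10`.
#'
#' @param net_discovery,net_replication gene x gene network matrices
#'   (adjacency or change matrices) over the same gene universe.
#' @param module character vector of member genes.
#' @param n_perm random gene sets for the null (default 200).
#' @param seed resampling seed.
#' @return one-row data.frame: `z_density`, `z_connectivity`, `z_summary`,
#'   `preserved`.
#' @export
preservation_zsummary <- function(net_discovery, net_replication, module,
                                  n_perm = 200, seed = 1L) {
  genes <- rownames(net_replication)
  if (!identical(genes, rownames(net_discovery)))
    stopf("discovery and replication networks must share the same gene universe")
  idx <- match(module, genes)
  if (anyNA(idx)) stopf("module gene(s) absent from the networks")
  m <- length(idx)
  if (m > length(genes) / 2)
    stopf("module size exceeds half the gene universe; null resampling is degenerate")

  stat_pair <- function(ix) {
    sub_r <- net_replication[ix, ix]
    sub_d <- net_discovery[ix, ix]
    off <- upper.tri(sub_r)
    density <- mean(sub_r[off])
    k_d <- rowSums(sub_d) - diag(sub_d)
    k_r <- rowSums(sub_r) - diag(sub_r)
    connectivity <- if (stats::sd(k_d) == 0 || stats::sd(k_r) == 0) 0
                    else stats::cor(k_d, k_r)
    c(density, connectivity)
  }

  obs <- stat_pair(idx)
  null_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat_pair(sample.int(length(genes), m)), numeric(2)))
  mu <- rowMeans(null_stats)
  sdv <- apply(null_stats, 1, stats::sd)
  z <- (obs - mu) / ifelse(sdv > 0, sdv, NA_real_)
  z_summary <- mean(z)
  data.frame(z_density = z[1], z_connectivity = z[2], z_summary = z_summary,
             preserved = isTRUE(z_summary > 10))
}

#' Export per-module differential-correlation heatmaps
#'
#' For each module, writes a PNG heatmap with the case correlations in the
#' upper triangle and the control correlations in the lower triangle,
#' genes ordered by average-linkage clustering of the correlation values,
#' plus a numeric tab-separated sidecar of the displayed matrix.
#'
#' @param expr_cases,expr_controls probe x sample matrices (same genes).
#' @param modules a module assignment.
#' @param dir output directory.
#' @return invisibly, the named list of written matrix files.
#' @export
dc_heatmap_export <- function(expr_cases, expr_controls, modules, dir) {
  mods <- setdiff(unique(modules$module), "unassigned")
  if (length(mods) == 0) stopf("no modules to export")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- list()
  for (m in mods) {
    genes <- modules$gene[modules$module == m]
    rc <- spearman_cor(t(expr_cases[genes, , drop = FALSE]))
    rt <- spearman_cor(t(expr_controls[genes, , drop = FALSE]))
    ord <- stats::hclust(stats::as.dist(1 - (rc + rt) / 2), method = "average")$order
    rc <- rc[ord, ord]; rt <- rt[ord, ord]
    combined <- rt
    combined[upper.tri(combined)] <- rc[upper.tri(rc)]
    diag(combined) <- 1
    mat_path <- file.path(dir, sprintf("dc_heatmap_%s.tsv", m))
    utils::write.table(round(combined, 4), mat_path, sep = "\t", quote = FALSE)
    png_path <- file.path(dir, sprintf("dc_heatmap_%s.png", m))
    grDevices::png(png_path, width = 640, height = 640)
    graphics::image(t(combined[rev(seq_len(nrow(combined))), ]),
                    zlim = c(-1, 1), axes = FALSE,
                    col = grDevices::hcl.colors(51, "Blue-Red 2"),
                    main = sprintf("Module %s: cases (upper) vs controls (lower)", m))
    grDevices::dev.off()
    written[[m]] <- mat_path
  }
  invisible(written)
}
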