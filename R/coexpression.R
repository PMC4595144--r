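#' Build a weighted co-expression adjacency matrix
#'
#' Pairwise Spearman rank correlations (midranks for ties; robust to
#' influential outliers) raised to a soft-threshold power:
#' `a_ij = |rho_ij|^beta` for the unsigned network (default) or
#' `a_ij = ((1 + rho_ij)/2)^beta` for the signed variant.
#'
#' @param expr probe x sample matrix (typically covariate-adjusted
#'   residuals).
#' @param beta soft-threshold power (>= 1, default 6).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return gene x gene adjacency matrix in `[0, 1]` with unit diagonal;
#'   `beta` and `type` are attached as attributes.
#' @export
build_adjacency <- function(expr, beta = 6, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) stopf("beta must be >= 1")
  if (ncol(expr) < 3) stopf("need at least 3 samples")
  rho <- spearman_cor(t(expr))
  a <- if (type == "unsigned") abs(rho)^beta else ((1 + rho) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "type") <- type
  a
}

#' Extract modules from an adjacency (or similarity) matrix
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `1 - a`, with a static cut at `cut_height`. Clusters smaller than
#' `min_module_size` are relabeled `"unassigned"`; surviving modules are
#' named from a fixed colour palette in order of descending size
#' (turquoise, blue, brown, ...), or in seeded random order when
#' `shuffle_colors` is set (the convention for differential-co-expression
#' modules).
#'
#' @param adj gene x gene matrix in `[0, 1]` (large = similar).
#' @param cut_height static tree-cut height in `(0, 1]` (default 0.96).
#' @param min_module_size smallest reportable module (default 30).
#' @param shuffle_colors randomly permute colour labels (seeded).
#' @param seed seed for the colour shuffle.
#' @return a `module_assignment` data.frame (`gene`, `module`) with the
#'   `hclust` tree, cut height and minimum size attached as attributes.
#' @export
extract_modules <- function(adj, cut_height = 0.96, min_module_size = 30,
                            shuffle_colors = FALSE, seed = 1L) {
  if (cut_height <= 0 || cut_height > 1) stopf("cut_height must be in (0, 1]")
  genes <- rownames(adj)
  diss <- 1 - adj
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("unassigned", length(cl))
  if (length(big) > 0) {
    ord <- big[order(-sizes[big], as.integer(big))]
    colors <- module_palette(length(ord))
    if (shuffle_colors) colors <- with_seed(seed, sample(colors))
    for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- colors[i]
  }
  out <- data.frame(gene = genes, module = labels, stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- cut_height
  attr(out, "min_module_size") <- min_module_size
  class(out) <- c("module_assignment", "data.frame")
  out
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- sort(table(x$module[x$module != "unassigned"]), decreasing = TRUE)
  cat(sprintf("Module assignment: %d genes, %d modules (cut height %.2f, min size %d)\n",
              nrow(x), length(tab), attr(x, "cut_height"), attr(x, "min_module_size")))
  if (length(tab) > 0)
    cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  unassigned: %d\n", sum(x$module == "unassigned")))
  invisible(x)
}

#' Co-differential co-expression test
#'
#' Matches each gene's differential-expression significance
#' `GS = -log10(p)` to its module and asks, per module, whether the mean
#' gene significance is higher than expected by chance: the null draws
#' `n_perm` random gene sets of the same size from all genes in the
#' assignment universe, and `p_perm = (r + 1) / (n_perm + 1)` where `r`
#' counts null means at or above the observed mean.
#'
#' @param modules a [extract_modules()] assignment.
#' @param de a [logistic_de()] result covering every assigned gene.
#' @param n_perm number of null gene sets (>= 1000, default 10000).
#' @param seed seed for the resampling.
#' @return data.frame per module: `module`, `n_genes`,
#'   `mean_gene_significance`, `p_perm`.
#' @export
cdc_test <- function(modules, de, n_perm = 10000, seed = 1L) {
  if (n_perm < 1000) stopf("n_perm must be >= 1000")
  gs_all <- -log10(pmax(de$p, .Machine$double.xmin))
  names(gs_all) <- de$probe_id
  mods <- setdiff(unique(modules$module), "unassigned")
  if (length(mods) == 0)
    return(data.frame(module = character(0), n_genes = integer(0),
                      mean_gene_significance = numeric(0), p_perm = numeric(0)))
  missing <- setdiff(modules$gene, de$probe_id)
  if (length(missing) > 0)
    stopf("no DE p-value for gene(s): %s", paste(utils::head(missing, 5), collapse = ", "))
  universe <- gs_all[modules$gene]
  res <- with_seed(seed, {
    lapply(mods, function(m) {
      members <- modules$gene[modules$module == m]
      if (length(members) > length(universe)) stopf("module larger than gene universe")
      obs <- mean(gs_all[members])
      null_means <- vapply(seq_len(n_perm), function(i) {
        mean(universe[sample.int(length(universe), length(members))])
      }, numeric(1))
      r <- sum(null_means >= obs)
      data.frame(module = m, n_genes = length(members),
                 mean_gene_significance = obs,
                 p_perm = (r + 1) / (n_perm + 1), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
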