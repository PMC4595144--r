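#' Describe a planted co-expression module
#'
#' A planted module is a block of genes driven by a shared latent factor,
#' with separately targeted within-module correlations in cases and
#' controls. Setting `r_case = 0` while `r_control > 0` plants a loss of
#' co-expression in cases, the differential-co-expression signal the
#' downstream dispersion test is designed to detect.
#'
#' @param size number of genes in the module (>= 3).
#' @param r_case target pairwise within-module correlation among cases.
#' @param r_control target pairwise correlation among controls.
#' @param preserved_in_replication if `FALSE`, the module factor is planted
#'   only in the generator's suggested discovery subset
#'   (`metadata$set_suggested == "discovery"`), so the module dissolves in
#'   replication samples.
#' @return a `planted_module` list.
#' @export
planted_module <- function(size, r_case, r_control, preserved_in_replication = TRUE) {
  if (size < 3) stopf("planted_module: size must be >= 3 (got %d)", size)
  if (abs(r_case) > 1) stopf("planted_module: |r_case| must be <= 1")
  if (abs(r_control) > 1) stopf("planted_module: |r_control| must be <= 1")
  structure(
    list(size = as.integer(size), r_case = r_case, r_control = r_control,
         preserved_in_replication = isTRUE(preserved_in_replication)),
    class = "planted_module"
  )
}

#' Configure the synthetic case-control expression dataset
#'
#' Defaults emulate an Illumina HumanHT-12-style blood expression study of a
#' history of aneurysmal subarachnoid hemorrhage: 119 cases and 118
#' controls before quality control, log2-scale intensities around a
#' baseline of 7, chip-batch effects, eight sex-chromosome check probes,
#' and the quality-control failures the pipeline must catch (two
#' duplicates, nine principal-component outliers, eight low-RIN samples).
#'
#' @param n_cases,n_controls group sizes before quality control.
#' @param n_probes number of probes.
#' @param planted_modules list of [planted_module()] objects.
#' @param n_de_genes number of differentially expressed probes.
#' @param de_effect case-control mean difference for DE probes (log2 units).
#' @param n_batches number of technical batches (0 disables batch effects).
#' @param batch_sd per-probe batch offset SD (log2 units).
#' @param noise_sd residual probe noise SD (log2 units); must be > 0.
#' @param n_sex_probes number of sex-chromosome check probes.
#' @param sex_effect expression shift in males on sex probes (log2 units).
#' @param n_duplicates near-copy samples appended to the matrix.
#' @param n_outliers samples mean-shifted to separate on PC1.
#' @param n_low_rin samples given an RNA integrity number below 6.
#' @param seed integer seed; the dataset is a pure function of config + seed.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_cases = 119, n_controls = 118,
                              n_probes = 34135, planted_modules = list(),
                              n_de_genes = 0, de_effect = 1,
                              n_batches = 4, batch_sd = 0.3,
                              noise_sd = 1, n_sex_probes = 8, sex_effect = 3,
                              n_duplicates = 2, n_outliers = 9,
                              n_low_rin = 8, seed = 1L) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls, n_probes = n_probes,
    planted_modules = planted_modules, n_de_genes = n_de_genes,
    de_effect = de_effect, n_batches = n_batches, batch_sd = batch_sd,
    noise_sd = noise_sd, n_sex_probes = n_sex_probes, sex_effect = sex_effect,
    n_duplicates = n_duplicates, n_outliers = n_outliers,
    n_low_rin = n_low_rin, seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_cases", "n_controls", "n_probes", "n_de_genes", "n_batches",
              "n_sex_probes", "n_duplicates", "n_outliers", "n_low_rin")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v))
      stopf("simulation config: field '%s' must be a non-negative count", f)
    cfg[[f]] <- as.integer(v)
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stopf("simulation config: field 'noise_sd' must be > 0")
  if (cfg$batch_sd < 0) stopf("simulation config: field 'batch_sd' must be >= 0")
  for (m in cfg$planted_modules) {
    if (!inherits(m, "planted_module"))
      stopf("simulation config: field 'planted_modules' must hold planted_module objects")
  }
  planted_total <- sum(vapply(cfg$planted_modules, `[[`, integer(1), "size"))
  reserved <- planted_total + cfg$n_de_genes + cfg$n_sex_probes
  if (reserved > cfg$n_probes)
    stopf("simulation config: planted modules + DE genes + sex probes (%d) exceed field 'n_probes' (%d)",
          reserved, cfg$n_probes)
  n <- cfg$n_cases + cfg$n_controls
  if (cfg$n_outliers + cfg$n_duplicates > n)
    stopf("simulation config: fields 'n_outliers'/'n_duplicates' exceed sample count")
  if (cfg$n_low_rin > n)
    stopf("simulation config: field 'n_low_rin' exceeds sample count")
  class(cfg) <- "simulation_config"
  cfg
}

# stratified 2/3 suggested-discovery labels, used for non-preserved modules
suggest_split <- function(is_case) {
  lab <- rep("discovery", length(is_case))
  for (grp in c(TRUE, FALSE)) {
    idx <- which(is_case == grp)
    n_rep <- floor(length(idx) / 3)
    lab[sample(idx, n_rep)] <- "replication"
  }
  lab
}

#' Generate a synthetic case-control expression dataset with known truth
#'
#' Builds a raw-intensity probe x sample matrix (`2^z` of a Gaussian
#' log2-scale model) plus metadata and probe annotation. Planted structure:
#' co-expression modules follow a single-factor model
#' `z = sqrt(r) * factor + sqrt(1 - r) * noise` (scaled by `noise_sd`) so the
#' expected pairwise within-module correlation equals the target `r` in each
#' group; DE probes differ in group mean by `de_effect`; sex probes are
#' shifted in males; duplicates are near-copies (correlation > 0.99) of
#' existing samples; outliers are mean-shifted by 10 noise SDs; low-RIN
#' samples draw RIN below 6.
#'
#' @param config a [simulation_config()].
#' @return a `dcoex_dataset` list: `expression` (raw intensities),
#'   `metadata`, `annotation`, `truth` (per-probe module label and DE flag),
#'   `truth_samples` (per-sample duplicate/outlier/low-quality flags).
#' @export
generate_dataset <- function(config) {
  config <- validate_simulation_config(unclass(config))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_cases + cfg$n_controls
  p <- cfg$n_probes
  is_case <- c(rep(TRUE, cfg$n_cases), rep(FALSE, cfg$n_controls))
  sample_id <- c(sprintf("CASE%03d", seq_len(cfg$n_cases)),
                 sprintf("CTRL%03d", seq_len(cfg$n_controls)))

  # --- metadata, roughly matching the study's baseline characteristics
  female <- ifelse(is_case, stats::runif(n) < 0.83, stats::runif(n) < 0.40)
  md <- data.frame(
    sample_id = sample_id,
    is_case = is_case,
    age = round(pmin(87, pmax(20, stats::rnorm(n, 60, 10)))),
    reported_sex = ifelse(female, "F", "M"),
    hypertension = ifelse(is_case, stats::runif(n) < 0.61, stats::runif(n) < 0.28),
    smoking_ever = ifelse(is_case, stats::runif(n) < 0.83, stats::runif(n) < 0.78),
    familial_ia = is_case & stats::runif(n) < 0.04,
    rin = pmin(10, pmax(6, stats::rnorm(n, 8.2, 0.8))),
    ratio_260_280 = round(stats::rnorm(n, 1.95, 0.05), 2),
    batch = if (cfg$n_batches > 0) sample(cfg$n_batches, n, replace = TRUE) else rep(1L, n),
    stringsAsFactors = FALSE
  )
  # leukocyte differential counts (10^9/L), same distribution in both groups
  md$leuko_neutrophils <- round(stats::rlnorm(n, log(4.0), 0.25), 2)
  md$leuko_lymphocytes <- round(stats::rlnorm(n, log(2.0), 0.25), 2)
  md$leuko_monocytes   <- round(stats::rlnorm(n, log(0.5), 0.25), 2)
  md$leuko_eosinophils <- round(stats::rlnorm(n, log(0.15), 0.35), 2)
  md$leuko_basophils   <- round(stats::rlnorm(n, log(0.05), 0.35), 3)
  md$set_suggested <- suggest_split(is_case)

  low_rin <- if (cfg$n_low_rin > 0) sample(n, cfg$n_low_rin) else integer(0)
  md$rin[low_rin] <- round(stats::runif(cfg$n_low_rin, 4, 5.9), 1)

  # --- probe annotation; planted probes stay specific, autosomal, current
  probe_id <- sprintf("PRB%05d", seq_len(p))
  sex_idx <- if (cfg$n_sex_probes > 0) p - cfg$n_sex_probes + seq_len(cfg$n_sex_probes) else integer(0)
  autosomal <- setdiff(seq_len(p), sex_idx)
  chromosome <- character(p)
  chromosome[autosomal] <- as.character(sample(1:22, length(autosomal), replace = TRUE))
  chromosome[sex_idx] <- rep(c("X", "Y"), length.out = length(sex_idx))

  planted_sizes <- vapply(cfg$planted_modules, `[[`, integer(1), "size")
  mod_idx <- if (length(planted_sizes) > 0) {
    split(seq_len(sum(planted_sizes)), rep(seq_along(planted_sizes), planted_sizes))
  } else list()
  de_idx <- if (cfg$n_de_genes > 0) sum(planted_sizes) + seq_len(cfg$n_de_genes) else integer(0)
  planted <- c(unlist(mod_idx), de_idx)

  is_specific <- rep(TRUE, p)
  is_retired <- rep(FALSE, p)
  free_idx <- setdiff(autosomal, planted)
  is_specific[sample(free_idx, round(0.03 * length(free_idx)))] <- FALSE
  is_retired[sample(free_idx, round(0.01 * length(free_idx)))] <- TRUE
  annotation <- data.frame(
    probe_id = probe_id,
    chromosome = chromosome,
    is_specific = is_specific,
    is_retired = is_retired,
    gene_symbol = sprintf("GENE%05d", ceiling(seq_len(p) / 1.05)),
    is_sex_check_probe = seq_len(p) %in% sex_idx,
    stringsAsFactors = FALSE
  )

  # --- log2-scale expression model
  baseline <- stats::rnorm(p, 7, 0.6)
  z <- matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n)
  if (cfg$n_batches > 0 && cfg$batch_sd > 0) {
    beff <- matrix(stats::rnorm(p * cfg$n_batches, 0, cfg$batch_sd), p, cfg$n_batches)
    z <- z + beff[, md$batch]
  }
  for (k in seq_along(cfg$planted_modules)) {
    pm <- cfg$planted_modules[[k]]
    rows <- mod_idx[[k]]
    active <- if (pm$preserved_in_replication) rep(TRUE, n) else md$set_suggested == "discovery"
    f <- numeric(n)
    f[active] <- as.vector(scale(stats::rnorm(sum(active)))) # unit sample variance
    r_target <- ifelse(is_case, pm$r_case, pm$r_control)
    # sign-alternating loadings realise negative correlation targets
    sgn <- if (min(pm$r_case, pm$r_control) < 0) rep_len(c(1, -1), length(rows)) else rep(1, length(rows))
    for (j in which(active)) {
      r <- r_target[j]
      z[rows, j] <- cfg$noise_sd *
        (sgn * sqrt(abs(r)) * f[j] + sqrt(1 - abs(r)) * stats::rnorm(length(rows)))
    }
  }
  if (length(de_idx) > 0) z[de_idx, is_case] <- z[de_idx, is_case] + cfg$de_effect
  if (length(sex_idx) > 0) {
    # sex-marker transcripts are tightly bimodal on real arrays: shrink
    # their residual noise so the two sexes form clean clusters
    z[sex_idx, ] <- 0.2 * z[sex_idx, ]
    male <- md$reported_sex == "M"
    z[sex_idx, male] <- z[sex_idx, male] + cfg$sex_effect
  }
  z <- z + baseline

  outliers <- if (cfg$n_outliers > 0) sample(n, cfg$n_outliers) else integer(0)
  z[, outliers] <- z[, outliers] + 10 * cfg$noise_sd

  # duplicates: near-copies of clean samples, appended after the originals
  dup_src <- if (cfg$n_duplicates > 0) sample(setdiff(seq_len(n), outliers), cfg$n_duplicates) else integer(0)
  if (length(dup_src) > 0) {
    zd <- z[, dup_src, drop = FALSE] +
      matrix(stats::rnorm(p * length(dup_src), 0, 0.05), p)
    z <- cbind(z, zd)
    md_dup <- md[dup_src, , drop = FALSE]
    md_dup$sample_id <- paste0(md$sample_id[dup_src], "_DUP")
    md <- rbind(md, md_dup)
  }
  rownames(md) <- NULL
  dimnames(z) <- list(probe_id, md$sample_id)

  truth_module <- rep(NA_character_, p)
  for (k in seq_along(mod_idx)) truth_module[mod_idx[[k]]] <- paste0("M", k)
  truth <- data.frame(
    probe_id = probe_id, module = truth_module,
    is_de = seq_len(p) %in% de_idx, stringsAsFactors = FALSE
  )
  truth_samples <- data.frame(
    sample_id = md$sample_id,
    is_duplicate = grepl("_DUP$", md$sample_id),
    is_outlier = seq_len(nrow(md)) %in% outliers,
    is_low_quality = md$rin < 6 | md$ratio_260_280 < 1.8,
    stringsAsFactors = FALSE
  )

  structure(
    list(expression = 2^z, metadata = md, annotation = annotation,
         truth = truth, truth_samples = truth_samples, config = cfg),
    class = "dcoex_dataset"
  )
}

#' @export
print.dcoex_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic expression dataset: %d probes x %d samples (%d cases, %d controls)\n",
    nrow(x$expression), ncol(x$expression),
    sum(x$metadata$is_case), sum(!x$metadata$is_case)
  ))
  cat(sprintf("  planted modules: %d; DE probes: %d; duplicates: %d; outliers: %d\n",
              length(x$config$planted_modules), sum(x$truth$is_de),
              sum(x$truth_samples$is_duplicate), sum(x$truth_samples$is_outlier)))
  invisible(x)
}
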