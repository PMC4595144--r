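# End-to-end pipeline: QC -> split -> surrogate-variable adjustment -> DE
# (two-stage) -> co-expression + CDC -> differential co-expression with
# permutation inference and preservation -> hub scoring -> NSC classifier.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    input = NULL,    # list(expression=, metadata=, annotation=) of file paths
    simulate = NULL, # arguments for simulation_config()
    qc = list(rin_min = 6, purity_min = 1.8, k_mad = 5, min_discordant = 2,
              r_min = 0.99),
    adjust = list(n_sv = "auto",
                  known_covariates = c("age", "reported_sex", "hypertension",
                                       "smoking_ever", "familial_ia")),
    de = list(alpha_fdr = 0.05, candidate_genes = NULL),
    network = list(beta = 6, cut_height = 0.96, min_module_size = 30,
                   cdc_n_perm = 10000),
    dc = list(n_perm = 10000, alpha = 0.05, preservation_n_perm = 200,
              export_heatmaps = FALSE),
    hubs = list(edge_quantile = 0.9),
    classify = list(n_folds = 10, error_ceiling = 0.4)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for all omitted keys, checks value ranges, and reports
#' every violation at once.
#'
#' @param config named list; recognized blocks are `seed`, `out_dir`,
#'   `input` (paths to expression/metadata/annotation tables) or
#'   `simulate` (arguments for [simulation_config()]), and the stage
#'   blocks `qc`, `adjust`, `de`, `network`, `dc`, `hubs`, `classify`.
#' @return the normalized config.
#' @export
validate_config <- function(config = list()) {
  defs <- default_config()
  merged <- utils::modifyList(defs, config)
  errors <- character(0)
  bad <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0) bad("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(merged$input) && is.null(merged$simulate))
    bad("either 'input' paths or a 'simulate' block is required")
  if (!is.null(merged$input)) {
    need <- c("expression", "metadata", "annotation")
    for (f in need) {
      if (is.null(merged$input[[f]])) bad("input.%s is required", f)
      else if (!file.exists(merged$input[[f]])) bad("input.%s: file not found (%s)", f, merged$input[[f]])
    }
  }
  in_range <- function(key, val, lo, hi, open_lo = FALSE, open_hi = FALSE) {
    ok <- is.numeric(val) && length(val) == 1 && !is.na(val) &&
      (if (open_lo) val > lo else val >= lo) &&
      (if (open_hi) val < hi else val <= hi)
    if (!ok) bad("%s: must be in %s%g, %g%s (got %s)", key,
                 if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]",
                 paste(val, collapse = ","))
  }
  in_range("network.cut_height", merged$network$cut_height, 0, 1, open_lo = TRUE)
  in_range("network.beta", merged$network$beta, 1, Inf)
  in_range("network.min_module_size", merged$network$min_module_size, 2, Inf)
  in_range("de.alpha_fdr", merged$de$alpha_fdr, 0, 1, open_lo = TRUE)
  in_range("dc.n_perm", merged$dc$n_perm, 100, Inf)
  in_range("dc.alpha", merged$dc$alpha, 0, 1, open_lo = TRUE)
  in_range("hubs.edge_quantile", merged$hubs$edge_quantile, 0, 1, TRUE, TRUE)
  in_range("classify.n_folds", merged$classify$n_folds, 2, Inf)
  in_range("classify.error_ceiling", merged$classify$error_ceiling, 0, 1, open_lo = TRUE)
  in_range("qc.rin_min", merged$qc$rin_min, 0, Inf, open_lo = TRUE)
  in_range("qc.r_min", merged$qc$r_min, 0, 1, TRUE, TRUE)
  if (!identical(merged$adjust$n_sv, "auto")) in_range("adjust.n_sv", merged$adjust$n_sv, 0, Inf)
  if (length(errors) > 0)
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  # planted modules supplied as plain lists (e.g. from YAML) are upgraded
  if (!is.null(merged$simulate$planted_modules)) {
    merged$simulate$planted_modules <- lapply(
      merged$simulate$planted_modules,
      function(m) if (inherits(m, "planted_module")) m else do.call(planted_module, m)
    )
  }
  merged
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the blocks accepted by [validate_config()].
#' @return the validated, normalized configuration.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

read_candidate_genes <- function(path) {
  genes <- trimws(readLines(path))
  genes[nzchar(genes)]
}

#' Run the full case-control co-expression pipeline
#'
#' Executes, under one global seed: quality control; stratified
#' discovery/replication split; surrogate-variable estimation;
#' differential expression with two-stage replication and (optionally)
#' candidate-gene lookup; co-expression modules with the co-differential
#' co-expression test; differential co-expression with dispersion-
#' statistic permutation inference; Z-summary preservation and hub scoring
#' for modules passing the Bonferroni gate; and the nearest shrunken
#' centroid classifier with cross-validated shrinkage evaluated on the
#' replication set. Per-stage seeds are derived deterministically from the
#' global seed.
#'
#' @param config a pipeline configuration (see [validate_config()]).
#' @return a `pipeline_result` list of per-stage outputs plus `report`,
#'   a deterministic summary; when `config$out_dir` is set the report and
#'   stage tables are also written there.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  seed <- as.integer(cfg$seed)

  # --- input
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- derive_seed(seed, "simulate")
    dataset <- generate_dataset(do.call(simulation_config, sim_args))
    expr <- dataset$expression; md <- dataset$metadata; annot <- dataset$annotation
  } else {
    dataset <- NULL
    expr <- read_expression(cfg$input$expression)
    md <- read_metadata(cfg$input$metadata)
    annot <- read_annotation(cfg$input$annotation)
  }

  # --- quality control
  qc <- run_qc(expr, md, annot, rin_min = cfg$qc$rin_min,
               purity_min = cfg$qc$purity_min, k_mad = cfg$qc$k_mad,
               min_discordant = cfg$qc$min_discordant, r_min = cfg$qc$r_min)
  md_qc <- qc$metadata

  # --- discovery/replication split
  split <- split_discovery_replication(md_qc, seed = derive_seed(seed, "split"))
  disc_ids <- split$sample_id[split$set_label == "discovery"]
  repl_ids <- split$sample_id[split$set_label == "replication"]
  e_disc <- qc$expression[, disc_ids, drop = FALSE]
  e_repl <- qc$expression[, repl_ids, drop = FALSE]
  md_disc <- md_qc[match(disc_ids, md_qc$sample_id), ]
  md_repl <- md_qc[match(repl_ids, md_qc$sample_id), ]

  # --- surrogate variables + differential expression (discovery)
  sv_disc <- estimate_surrogate_variables(e_disc, md_disc$is_case,
                                          n_sv = cfg$adjust$n_sv,
                                          seed = derive_seed(seed, "sva"))
  de_disc <- logistic_de(e_disc, md_disc$is_case, covariates = sv_disc$sv)
  sv_repl <- estimate_surrogate_variables(e_repl, md_repl$is_case,
                                          n_sv = cfg$adjust$n_sv,
                                          seed = derive_seed(seed, "sva") + 1L)
  two_stage <- two_stage_replication(de_disc, e_repl, md_repl$is_case,
                                     covariates = sv_repl$sv,
                                     alpha_fdr = cfg$de$alpha_fdr)
  candidate <- NULL
  if (!is.null(cfg$de$candidate_genes)) {
    genes <- read_candidate_genes(cfg$de$candidate_genes)
    candidate <- candidate_gene_lookup(
      de_disc, genes,
      annot[, c("probe_id", "gene_symbol")]
    )
  }

  # --- leukocyte counts and known-risk-factor residuals (CDC substrate)
  leuko <- compare_leukocyte_counts(md_qc)
  # covariates that are constant within a set (e.g. familial IA absent from
  # a small replication set) carry no adjustment information and are dropped
  usable_covs <- function(md) {
    covs <- md[, intersect(cfg$adjust$known_covariates, names(md)), drop = FALSE]
    covs[, vapply(covs, function(v) length(unique(v)) > 1, logical(1)), drop = FALSE]
  }
  resid_disc <- residualize(e_disc, usable_covs(md_disc))$values
  resid_repl <- residualize(e_repl, usable_covs(md_repl))$values

  # --- co-expression modules + CDC test
  adj <- build_adjacency(resid_disc, beta = cfg$network$beta)
  coexp_modules <- extract_modules(adj, cut_height = cfg$network$cut_height,
                                   min_module_size = cfg$network$min_module_size)
  cdc <- cdc_test(coexp_modules, de_disc, n_perm = max(1000, cfg$network$cdc_n_perm),
                  seed = derive_seed(seed, "cdc"))

  # --- differential co-expression
  case_d <- resid_disc[, md_disc$is_case, drop = FALSE]
  ctrl_d <- resid_disc[, !md_disc$is_case, drop = FALSE]
  d_disc <- dc_dissimilarity(case_d, ctrl_d, beta = cfg$network$beta)
  dc_modules <- extract_dc_modules(d_disc, cut_height = cfg$network$cut_height,
                                   min_module_size = cfg$network$min_module_size,
                                   seed = derive_seed(seed, "dc"))
  dispersion <- dc_permutation_test(case_d, ctrl_d, dc_modules,
                                    n_perm = cfg$dc$n_perm, beta = cfg$network$beta,
                                    seed = derive_seed(seed, "dc"))

  # --- preservation of Bonferroni-significant DC modules in replication
  significant <- dispersion$module[dispersion$p_bonf < cfg$dc$alpha]
  preservation <- NULL
  if (length(significant) > 0) {
    case_r <- resid_repl[, md_repl$is_case, drop = FALSE]
    ctrl_r <- resid_repl[, !md_repl$is_case, drop = FALSE]
    d_repl <- dc_dissimilarity(case_r, ctrl_r, beta = cfg$network$beta)
    preservation <- do.call(rbind, lapply(significant, function(m) {
      genes <- dc_modules$gene[dc_modules$module == m]
      cbind(module = m,
            preservation_zsummary(d_disc, d_repl, genes,
                                  n_perm = cfg$dc$preservation_n_perm,
                                  seed = derive_seed(seed, "preservation")))
    }))
  }

  # --- hubs: only modules passing both the permutation and preservation gates
  hub_modules <- if (is.null(preservation)) character(0) else
    preservation$module[preservation$preserved]
  hubs <- list()
  for (m in hub_modules) {
    genes <- dc_modules$gene[dc_modules$module == m]
    g <- build_module_graph(d_disc, genes, edge_quantile = cfg$hubs$edge_quantile)
    hubs[[m]] <- hub_scores(graph_metrics(g))
  }

  # --- nearest shrunken centroid classifier on SV-adjusted expression
  nsc_disc <- if (sv_disc$n_sv > 0) residualize(e_disc, as.data.frame(sv_disc$sv))$values else e_disc
  nsc_repl <- if (sv_repl$n_sv > 0) residualize(e_repl, as.data.frame(sv_repl$sv))$values else e_repl
  model <- nsc_cv(nsc_disc, md_disc$is_case, n_folds = cfg$classify$n_folds,
                  seed = derive_seed(seed, "classify"))
  prediction <- predict(model, nsc_repl, status = md_repl$is_case)
  gene_set <- smallest_gene_set_report(model, nsc_repl, md_repl$is_case,
                                       error_ceiling = cfg$classify$error_ceiling)

  report <- list(
    seed = seed,
    qc = list(n_samples_retained = qc$report$n_samples_retained,
              n_probes_retained = qc$report$n_probes_retained,
              sample_exclusions = as.list(table(qc$report$excluded_samples$reason)),
              probe_exclusions = as.list(table(qc$report$excluded_probes$reason))),
    split = list(n_discovery = length(disc_ids), n_replication = length(repl_ids)),
    adjust = list(n_sv_discovery = sv_disc$n_sv, n_sv_replication = sv_repl$n_sv),
    de = list(n_discovery_significant = length(two_stage$selected),
              n_replicated = length(two_stage$replicated),
              n_candidate_probes = if (is.null(candidate)) NA_integer_ else nrow(candidate),
              n_candidate_significant = if (is.null(candidate)) NA_integer_ else sum(candidate$significant)),
    leukocytes = list(min_p = min(leuko$p)),
    cdc = list(n_modules = nrow(cdc),
               min_p_perm = if (nrow(cdc) > 0) min(cdc$p_perm) else NA_real_),
    dc = list(n_modules = nrow(dispersion),
              n_significant = length(significant),
              n_preserved = if (is.null(preservation)) 0L else sum(preservation$preserved)),
    hubs = lapply(hubs, function(h) sum(h$is_hub)),
    classifier = list(cv_error = min(model$cv_errors),
                      chosen_delta = model$chosen_delta,
                      replication_misclassification = prediction$misclassification,
                      sensitivity = prediction$sensitivity,
                      specificity = prediction$specificity,
                      smallest_set_size = length(gene_set$genes),
                      smallest_set_qualified = gene_set$qualified)
  )

  result <- structure(list(
    config = cfg, dataset = dataset, qc = qc, split = split,
    surrogate = list(discovery = sv_disc, replication = sv_repl),
    de = de_disc, two_stage = two_stage, candidate = candidate,
    leukocytes = leuko, adjacency_modules = coexp_modules, cdc = cdc,
    dc_modules = dc_modules, dispersion = dispersion,
    preservation = preservation, hubs = hubs,
    classifier = model, prediction = prediction, gene_set = gene_set,
    report = report
  ), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_table_tsv(result$de, file.path(dir, "differential_expression.tsv"))
  write_table_tsv(result$dc_modules, file.path(dir, "dc_modules.tsv"))
  write_table_tsv(result$dispersion, file.path(dir, "dispersion.tsv"))
  if (!is.null(result$preservation))
    write_table_tsv(result$preservation, file.path(dir, "preservation.tsv"))
  for (m in names(result$hubs))
    write_table_tsv(result$hubs[[m]], file.path(dir, sprintf("hubs_%s.tsv", m)))
  write_table_tsv(result$prediction$table, file.path(dir, "replication_probabilities.tsv"))
  txt <- file.path(dir, "report.txt")
  writeLines(utils::capture.output(print(result)), txt)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Case-control co-expression pipeline report\n")
  cat(sprintf("  QC: %d samples, %d probes retained\n",
              r$qc$n_samples_retained, r$qc$n_probes_retained))
  cat(sprintf("  Split: %d discovery / %d replication\n",
              r$split$n_discovery, r$split$n_replication))
  cat(sprintf("  Surrogate variables: %d (discovery)\n", r$adjust$n_sv_discovery))
  cat(sprintf("  DE: %d discovery-significant, %d replicated\n",
              r$de$n_discovery_significant, r$de$n_replicated))
  cat(sprintf("  Co-expression modules: %d (min CDC p_perm %s)\n",
              r$cdc$n_modules, format(r$cdc$min_p_perm, digits = 3)))
  cat(sprintf("  DC modules: %d, %d significant (p_bonf < %.2f), %d preserved\n",
              r$dc$n_modules, r$dc$n_significant, x$config$dc$alpha, r$dc$n_preserved))
  cat(sprintf("  Classifier: CV error %.3f; replication misclassification %.3f (sens %.2f, spec %.2f)\n",
              r$classifier$cv_error, r$classifier$replication_misclassification,
              r$classifier$sensitivity, r$classifier$specificity))
  cat(sprintf("  Smallest gene set at error <= %.2f: %d genes (qualified: %s)\n",
              x$config$classify$error_ceiling, r$classifier$smallest_set_size,
              r$classifier$smallest_set_qualified))
  invisible(x)
}
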