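dc_fixture <- function(n_mod = 50, n_noise = 150, n_per_group = 70,
                       r_control = 0.7, r_case = 0, seed = 1) {
  mods <- if (n_mod > 0)
    list(planted_module(n_mod, r_case = r_case, r_control = r_control)) else list()
  ds <- generate_dataset(simulation_config(
    n_cases = n_per_group, n_controls = n_per_group, n_probes = n_mod + n_noise,
    planted_modules = mods,
    n_batches = 0, n_sex_probes = 0, n_duplicates = 0, n_outliers = 0,
    n_low_rin = 0, seed = seed))
  lg <- log2(ds$expression)
  list(cases = lg[, ds$metadata$is_case], controls = lg[, !ds$metadata$is_case],
       planted = ds$truth$probe_id[!is.na(ds$truth$module)], meta = ds$metadata,
       lg = lg)
}

test_that("the change matrix follows the signed-power difference formula", {
  set.seed(9)
  x <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("S%02d", 1:30)))
  d0 <- dc_dissimilarity(x, x, beta = 6)
  expect_true(all(d0 == 0)) # identical structure: no change anywhere
  # hand computation: rho_case 0.7, rho_control 0, beta 6
  expect_equal(round(sqrt(0.5 * 0.7^6), 4), 0.2425)
  # maximal change: rho +1 vs -1 gives d = 1 for any beta
  up <- rbind(G1 = 1:10, G2 = 1:10)
  down <- rbind(G1 = 1:10, G2 = 10:1)
  colnames(up) <- colnames(down) <- sprintf("S%02d", 1:10)
  expect_equal(unname(dc_dissimilarity(up, down, beta = 3)["G1", "G2"]), 1)
  expect_error(dc_dissimilarity(x, x[c(2:10, 1), ]), "same gene set")
})

test_that("the dispersion statistic is the RMS pairwise change", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(dispersion_statistic(d, c("a", "b", "c")), 0)
  d[upper.tri(d)] <- c(0.2, 0.4, 0.6)
  d <- d + t(d)
  expect_equal(dispersion_statistic(d, c("a", "b", "c")),
               sqrt((0.04 + 0.16 + 0.36) / 3), tolerance = 1e-12)
  expect_equal(round(dispersion_statistic(d, c("a", "b", "c")), 4), 0.4320)
  d1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(d1) <- 0
  expect_equal(dispersion_statistic(d1, letters[1:4]), 1)
  expect_error(dispersion_statistic(d, "a"), ">= 2")
})

test_that("DC module extraction isolates the planted block", {
  fx <- dc_fixture(seed = 23)
  d <- dc_dissimilarity(fx$cases, fx$controls, beta = 6)
  mods <- extract_dc_modules(d, seed = 5)
  assigned <- mods$gene[mods$module != "unassigned"]
  expect_gte(mean(fx$planted %in% assigned), 0.8)
  # with no group difference nothing clusters at the default cut
  null_fx <- dc_fixture(r_control = 0, r_case = 0, seed = 29)
  d0 <- dc_dissimilarity(null_fx$cases, null_fx$controls, beta = 6)
  m0 <- extract_dc_modules(d0, seed = 5)
  expect_true(all(m0$module == "unassigned"))
})

test_that("label permutation yields a valid null and trivial edge cases", {
  fx <- dc_fixture(n_mod = 20, n_noise = 20, n_per_group = 20, seed = 31)
  mods <- data.frame(gene = rownames(fx$cases),
                     module = c(rep("blue", 20), rep("unassigned", 20)))
  res <- dc_permutation_test(fx$cases, fx$controls, mods, n_perm = 200, seed = 3)
  expect_equal(res$n_genes, 20)
  expect_true(res$p_bonf >= res$p_emp)
  expect_equal(res$p_bonf, pmin(1, 1 * res$perm_index / 200))
  # identical groups: observed D_s = 0 is never exceeded, p_emp = 1
  same <- dc_permutation_test(fx$cases, fx$cases, mods, n_perm = 100, seed = 3)
  expect_equal(same$d_s, 0)
  expect_equal(same$perm_index, 100L)
  expect_equal(same$p_emp, 1)
  expect_error(dc_permutation_test(fx$cases, fx$controls, mods, n_perm = 50), "n_perm")
})

test_that("Z-summary separates preserved modules from random gene sets", {
  # module is a small fraction of the universe, as on a real array
  fx <- dc_fixture(n_mod = 50, n_noise = 450, n_per_group = 140, seed = 37)
  half <- seq_len(70)
  d_disc <- dc_dissimilarity(fx$cases[, half], fx$controls[, half], beta = 6)
  d_repl <- dc_dissimilarity(fx$cases[, -half], fx$controls[, -half], beta = 6)
  pres <- preservation_zsummary(d_disc, d_repl, fx$planted, n_perm = 100, seed = 2)
  expect_gt(pres$z_summary, 10)
  expect_true(pres$preserved)
  expect_error(preservation_zsummary(d_disc, d_repl, rownames(d_disc)[1:400]),
               "half the gene universe")
  # arbitrary gene sets in a structure-free dataset are not preserved
  nx <- dc_fixture(n_mod = 0, n_noise = 200, n_per_group = 100,
                   r_control = 0, seed = 43)
  nd_disc <- dc_dissimilarity(nx$cases[, 1:50], nx$controls[, 1:50], beta = 6)
  nd_repl <- dc_dissimilarity(nx$cases[, -(1:50)], nx$controls[, -(1:50)], beta = 6)
  z_rand <- vapply(1:10, function(s) {
    set.seed(s)
    genes <- sample(rownames(nd_disc), 30)
    preservation_zsummary(nd_disc, nd_repl, genes, n_perm = 100, seed = s)$z_summary
  }, numeric(1))
  expect_gte(mean(abs(z_rand) < 3), 0.9)
})

test_that("heatmap export writes images and numeric sidecars per module", {
  fx <- dc_fixture(n_mod = 20, n_noise = 10, n_per_group = 30, seed = 41)
  mods <- data.frame(gene = rownames(fx$cases),
                     module = c(rep("yellow", 20), rep("unassigned", 10)))
  dir <- withr::local_tempdir()
  files <- dc_heatmap_export(fx$cases, fx$controls, mods, dir)
  expect_true(file.exists(file.path(dir, "dc_heatmap_yellow.png")))
  expect_true(file.exists(file.path(dir, "dc_heatmap_yellow.tsv")))
  # identical groups produce a symmetric exported matrix
  dir2 <- withr::local_tempdir()
  dc_heatmap_export(fx$cases, fx$cases, mods, dir2)
  m <- as.matrix(read.delim(file.path(dir2, "dc_heatmap_yellow.tsv")))
  expect_equal(m[upper.tri(m)], t(m)[upper.tri(m)], tolerance = 1e-8)
  # planted module: mean case correlation differs from controls by ~ the gap
  m1 <- as.matrix(read.delim(file.path(dir, "dc_heatmap_yellow.tsv")))
  gap <- mean(m1[upper.tri(m1)]) - mean(t(m1)[upper.tri(m1)])
  expect_lt(abs(abs(gap) - 0.7), 0.2)
})
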