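make_meta <- function(rin, ratio, is_case = rep(c(TRUE, FALSE), length.out = length(rin))) {
  data.frame(sample_id = sprintf("S%02d", seq_along(rin)), is_case = is_case,
             rin = rin, ratio_260_280 = ratio, stringsAsFactors = FALSE)
}

test_that("lab-quality filter applies strict below-threshold rules", {
  md <- make_meta(rin = c(5, 6, 7, 5.9), ratio = c(1.9, 1.7, 1.9, 1.9))
  ex <- filter_lab_quality(md)
  expect_equal(ex$sample_id, c("S01", "S02", "S04"))
  expect_equal(ex$reason, c("low_rin", "low_purity", "low_rin"))
  # boundary values are retained: the rule is strictly "below"
  expect_equal(nrow(filter_lab_quality(make_meta(6.0, 1.8))), 0)
  expect_error(filter_lab_quality(make_meta(c(7, NA), c(1.9, 1.9))), "S02")
})

test_that("PC outlier detection flags exactly the shifted sample", {
  set.seed(1)
  x <- matrix(rnorm(100 * 61), 100, 61,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("S%02d", 1:61)))
  x[, 61] <- x[, 61] + 10
  out <- detect_pc_outliers(x)
  expect_equal(out$sample_id, "S61")
  expect_equal(nrow(detect_pc_outliers(x[, 1:60])), 0)
  expect_error(detect_pc_outliers(matrix(1, 5, 5,
    dimnames = list(paste0("p", 1:5), paste0("s", 1:5)))), "variance")
})

sex_fixture <- function(n_flip_probes = 0, flip_sample = 1) {
  n <- 24
  sex <- rep(c("M", "F"), each = n / 2)
  probes <- sprintf("SEXP%d", 1:8)
  set.seed(3)
  x <- matrix(rnorm(8 * n, 0, 0.2), 8, n, dimnames = list(probes, sprintf("S%02d", 1:n)))
  x <- x + 3 * matrix(rep(sex == "M", each = 8), 8, n)
  if (n_flip_probes > 0) {
    male <- sex[flip_sample] == "M"
    x[seq_len(n_flip_probes), flip_sample] <- rnorm(n_flip_probes, if (male) 0 else 3, 0.2)
  }
  annot <- data.frame(probe_id = probes, chromosome = "X", is_specific = TRUE,
                      is_retired = FALSE, is_sex_check_probe = TRUE,
                      stringsAsFactors = FALSE)
  md <- data.frame(sample_id = colnames(x), is_case = FALSE, reported_sex = sex,
                   stringsAsFactors = FALSE)
  list(x = x, annot = annot, md = md)
}

test_that("sex concordance needs at least two discordant probes to exclude", {
  clean <- sex_fixture()
  expect_equal(nrow(check_sex_concordance(clean$x, clean$annot, clean$md)), 0)
  one <- sex_fixture(n_flip_probes = 1)
  expect_equal(nrow(check_sex_concordance(one$x, one$annot, one$md)), 0)
  # relabelled sample: all 8 probes contradict the reported sex
  rel <- sex_fixture()
  rel$md$reported_sex[1] <- "F"
  ex <- check_sex_concordance(rel$x, rel$annot, rel$md)
  expect_equal(ex$sample_id, "S01")
  expect_gte(ex$n_discordant, 2)
  expect_error(check_sex_concordance(clean$x[1, , drop = FALSE],
                                     clean$annot[1, , drop = FALSE], clean$md),
               "sex-check probes")
})

test_that("duplicate groups keep exactly one, earliest, representative", {
  set.seed(7)
  base <- rnorm(200)
  x <- cbind(A = base + rnorm(200, 0, 0.01), B = rnorm(200),
             C = base + rnorm(200, 0, 0.01), D = base + rnorm(200, 0, 0.01))
  rownames(x) <- sprintf("P%03d", 1:200)
  ex <- detect_duplicates(x)
  expect_setequal(ex$sample_id, c("C", "D"))
  expect_true(all(ex$duplicate_of == "A"))
  noise <- matrix(rnorm(200 * 5), 200, 5,
                  dimnames = list(sprintf("P%03d", 1:200), LETTERS[1:5]))
  expect_equal(nrow(detect_duplicates(noise)), 0)
})

test_that("probe filters apply reason priority and reject unknown chromosomes", {
  annot <- data.frame(
    probe_id = sprintf("P%03d", 1:100),
    chromosome = c(rep("1", 92), rep("Y", 5), rep("2", 3)),
    is_specific = c(rep(FALSE, 10), rep(TRUE, 90)),
    is_retired = c(rep(FALSE, 97), rep(TRUE, 3)),
    stringsAsFactors = FALSE
  )
  ex <- filter_probes(annot)
  expect_equal(sum(ex$reason == "nonspecific"), 10)
  expect_equal(sum(ex$reason == "non_autosomal"), 5)
  expect_equal(sum(ex$reason == "retired"), 3)
  expect_equal(100 - nrow(ex), 82)
  # priority: a nonspecific chrX probe is reported as nonspecific
  both <- data.frame(probe_id = "P1", chromosome = "X", is_specific = FALSE,
                     is_retired = TRUE)
  expect_equal(filter_probes(both)$reason, "nonspecific")
  expect_error(filter_probes(data.frame(probe_id = "P1", chromosome = "chr_7",
                                        is_specific = TRUE, is_retired = FALSE)),
               "chromosome")
})

test_that("quantile normalization equalizes columns to per-rank means then log2", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  qn <- quantile_normalize_log2(x)
  for (j in 1:3) expect_equal(unname(sort(qn[, j])), log2(c(4, 5, 6)))
  # columns that are permutations of each other end up identical multisets
  y <- cbind(a = c(5, 1, 3), b = c(3, 5, 1), c = c(1, 3, 5))
  rownames(y) <- paste0("p", 1:3)
  qy <- quantile_normalize_log2(y)
  expect_equal(sort(qy[, "a"]), sort(qy[, "b"]), ignore_attr = TRUE)
  # already-identical columns are only log-transformed
  z <- matrix(rep(c(2, 4, 8), 3), 3, dimnames = dimnames(x))
  expect_equal(quantile_normalize_log2(z), log2(z))
  # idempotence of the rank-mean step
  expect_equal(quantile_normalize_log2(2^qn), qn)
  expect_error(quantile_normalize_log2(x - 2), "positive")
})

test_that("discovery/replication split is stratified, 2/3-1/3 and seeded", {
  md <- data.frame(sample_id = sprintf("S%03d", 1:210),
                   is_case = rep(c(TRUE, FALSE), c(103, 107)))
  sp <- split_discovery_replication(md, seed = 4)
  disc <- sp$set_label == "discovery"
  expect_equal(sum(disc & md$is_case), 103 - floor(103 / 3))   # 69
  expect_equal(sum(disc & !md$is_case), 107 - floor(107 / 3))  # 72
  expect_identical(sp, split_discovery_replication(md, seed = 4))
  tiny <- data.frame(sample_id = paste0("S", 1:6),
                     is_case = rep(c(TRUE, FALSE), each = 3))
  st <- split_discovery_replication(tiny, seed = 1)
  expect_equal(unname(table(st$set_label, tiny$is_case)["discovery", ]), c(2, 2))
  expect_error(split_discovery_replication(
    data.frame(sample_id = paste0("S", 1:4), is_case = c(TRUE, TRUE, FALSE, FALSE)),
    seed = 1), "stratum")
})

test_that("leukocyte comparison reproduces rank-sum arithmetic", {
  md <- data.frame(sample_id = paste0("S", 1:6),
                   is_case = rep(c(TRUE, FALSE), each = 3),
                   leuko_neutrophils = c(1, 2, 3, 10, 11, 12))
  res <- compare_leukocyte_counts(md)
  expect_equal(res$rank_sum, 6) # minimum possible rank sum for n = 3
  sym <- data.frame(sample_id = paste0("S", 1:4),
                    is_case = c(TRUE, TRUE, FALSE, FALSE),
                    leuko_lymphocytes = c(1, 2, 1, 2))
  expect_equal(compare_leukocyte_counts(sym)$p, 1)
  set.seed(8)
  shift <- data.frame(sample_id = paste0("S", 1:100),
                      is_case = rep(c(TRUE, FALSE), each = 50),
                      leuko_monocytes = rnorm(100) + rep(c(2, 0), each = 50))
  expect_lt(compare_leukocyte_counts(shift)$p, 0.05)
  expect_error(compare_leukocyte_counts(
    data.frame(sample_id = paste0("S", 1:3), is_case = c(TRUE, FALSE, FALSE),
               leuko_basophils = 1:3)), "2 observations")
})

test_that("full QC keeps the books balanced and is stable on clean data", {
  ds <- generate_dataset(simulation_config(
    n_cases = 40, n_controls = 40, n_probes = 300,
    n_duplicates = 2, n_outliers = 2, n_low_rin = 2, seed = 17))
  qc <- run_qc(ds$expression, ds$metadata, ds$annotation)
  rep <- qc$report
  expect_equal(rep$n_samples_retained + nrow(rep$excluded_samples), ncol(ds$expression))
  expect_equal(rep$n_probes_retained + nrow(rep$excluded_probes), nrow(ds$expression))
  expect_false(anyDuplicated(rep$excluded_samples$sample_id) > 0)
  # planted duplicates and outliers are all recovered at default thresholds
  planted_bad <- ds$truth_samples$sample_id[
    ds$truth_samples$is_duplicate | ds$truth_samples$is_outlier]
  expect_true(all(planted_bad %in% rep$excluded_samples$sample_id))
  # rerunning on the retained, cleaned data excludes nothing further
  qc2 <- run_qc(2^qc$expression, qc$metadata, qc$annotation)
  expect_equal(nrow(qc2$report$excluded_samples), 0)
  expect_equal(qc2$report$n_samples_retained, rep$n_samples_retained)
})
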