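test_that("shrunken centroids reproduce the closed-form toy computation", {
  # 2 genes x 6 samples, worked through the defining formulas by hand
  x <- rbind(G1 = c(1, 2, 3, 7, 8, 9),
             G2 = c(5, 5, 5, 5, 5, 5) + c(0.1, -0.1, 0, 0.1, -0.1, 0))
  colnames(x) <- sprintf("S%d", 1:6)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fit <- fit_nsc(x, y, delta_grid = c(0, 1))

  n <- 6; nk <- 3
  overall <- rowMeans(x)
  ctrl_mean <- rowMeans(x[, 1:3]); case_mean <- rowMeans(x[, 4:6])
  s_i <- sqrt((rowSums((x[, 1:3] - ctrl_mean)^2) +
               rowSums((x[, 4:6] - case_mean)^2)) / (n - 2))
  s0 <- median(s_i)
  mk <- sqrt(1 / nk - 1 / n)
  d_case <- (case_mean - overall) / (mk * (s_i + s0))
  expect_equal(unname(fit$d_ik[, "case"]), unname(d_case), tolerance = 1e-6)
  # delta = 0: shrunken centroids equal the raw class centroids
  cen0 <- shrunken_centroids(fit, 0)
  expect_equal(unname(cen0[, "case"]), unname(case_mean), tolerance = 1e-6)
  expect_equal(unname(cen0[, "control"]), unname(ctrl_mean), tolerance = 1e-6)
  # hand-shrunken centroid at delta = 1
  d_shr <- sign(d_case) * pmax(abs(d_case) - 1, 0)
  cen1 <- overall + mk * (s_i + s0) * d_shr
  expect_equal(unname(shrunken_centroids(fit, 1)[, "case"]), unname(cen1),
               tolerance = 1e-6)
  # delta beyond max |d|: everything collapses to the overall centroid
  big <- max(abs(fit$d_ik)) + 1
  expect_equal(length(active_genes(fit, big)), 0)
  expect_equal(unname(shrunken_centroids(fit, big)[, "case"]), unname(overall))
})

test_that("the active gene set shrinks monotonically along the delta grid", {
  for (s in 1:5) {
    dat <- make_signal_data(80, 10, 1.5, 25, 25, seed = s)
    fit <- fit_nsc(dat$x, dat$y)
    sizes <- vapply(fit$delta_grid, function(d) length(active_genes(fit, d)), integer(1))
    expect_true(all(diff(sizes) <= 0))
    expect_equal(sizes[1], 80) # delta 0 keeps every gene active
  }
})

test_that("delta = 0 predictions equal a plain nearest-centroid classifier", {
  dat <- make_signal_data(60, 8, 1, 20, 20, seed = 7)
  new <- make_signal_data(60, 8, 1, 15, 15, seed = 8)
  fit <- fit_nsc(dat$x, dat$y)
  pred <- predict(fit, new$x, delta = 0)
  oracle <- nearest_centroid_predict(dat$x, dat$y, new$x,
                                     fit$pooled_sd + fit$s0, fit$priors)
  expect_equal(unname(pred$class), unname(oracle))
})

test_that("class probabilities are proper and symmetric cases split 50/50", {
  dat <- make_signal_data(40, 5, 2, 20, 20, seed = 9)
  fit <- fit_nsc(dat$x, dat$y)
  pred <- predict(fit, dat$x)
  expect_equal(pred$table$prob_case + pred$table$prob_control,
               rep(1, nrow(pred$table)), tolerance = 1e-12)
  # equidistant sample with equal priors: exactly (0.5, 0.5), tie -> control
  x <- rbind(G1 = c(0, 0, 0, 2, 2, 2), G2 = c(1, 0, -1, 1, 0, -1))
  colnames(x) <- sprintf("S%d", 1:6)
  y <- rep(c(FALSE, TRUE), each = 3)
  f2 <- fit_nsc(x, y, delta_grid = 0, priors = c(0.5, 0.5))
  mid <- matrix(c(1, 0), 2, 1, dimnames = list(c("G1", "G2"), "M1"))
  pm <- predict(f2, mid, delta = 0)
  expect_equal(pm$table$prob_case, 0.5, tolerance = 1e-12)
  expect_equal(pm$class, "control") # tie-break
  # a sample at the case centroid is assigned to cases with p > 0.5
  at_case <- matrix(c(2, 0), 2, 1, dimnames = list(c("G1", "G2"), "C1"))
  expect_gt(predict(f2, at_case, delta = 0)$table$prob_case, 0.5)
})

test_that("cross-validation finds separable signal and prefers shrinkage", {
  dat <- make_signal_data(100, 20, 3, 25, 25, seed = 11)
  fit <- nsc_cv(dat$x, dat$y, n_folds = 5, seed = 2)
  expect_equal(min(fit$cv_errors), 0)
  expect_gt(fit$chosen_delta, 0) # ties resolved toward smaller gene sets
  # a one-point grid is chosen trivially
  f1 <- nsc_cv(dat$x, dat$y, delta_grid = 0.7, n_folds = 3, seed = 2)
  expect_equal(f1$chosen_delta, 0.7)
})

test_that("planted replication signal is classified with high sensitivity and specificity", {
  train <- make_signal_data(500, 50, 2, 70, 70, seed = 13)
  test <- make_signal_data(500, 50, 2, 35, 35, seed = 14)
  fit <- nsc_cv(train$x, train$y, n_folds = 5, seed = 3)
  pred <- predict(fit, test$x, status = test$y)
  expect_gte(pred$sensitivity, 0.9)
  expect_gte(pred$specificity, 0.9)
})

test_that("the smallest-gene-set scan respects the error ceiling", {
  # a diffuse planted signal needs many genes, so the qualifying set
  # overlaps the planted genes substantially
  train <- make_signal_data(200, 30, 0.6, 60, 60, seed = 1)
  test <- make_signal_data(200, 30, 0.6, 50, 50, seed = 101)
  fit <- fit_nsc(train$x, train$y)
  rep_any <- smallest_gene_set_report(fit, test$x, test$y, error_ceiling = 1.0)
  expect_true(rep_any$qualified)
  expect_gt(length(rep_any$genes), 0)
  rep_tight <- smallest_gene_set_report(fit, test$x, test$y, error_ceiling = 0.1)
  expect_true(rep_tight$qualified)
  planted <- sprintf("G%03d", 1:30)
  jac <- length(intersect(rep_tight$genes, planted)) /
    length(union(rep_tight$genes, planted))
  expect_gte(jac, 0.5)
  # pure noise cannot meet a 5% ceiling
  noise_tr <- make_signal_data(100, 0, 0, 30, 30, seed = 17)
  noise_te <- make_signal_data(100, 0, 0, 25, 25, seed = 18)
  fn <- fit_nsc(noise_tr$x, noise_tr$y)
  rn <- smallest_gene_set_report(fn, noise_te$x, noise_te$y, error_ceiling = 0.05)
  expect_false(rn$qualified)
  expect_equal(rn$genes, character(0))
})
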