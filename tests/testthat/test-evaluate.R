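test_that("normalized ranks average ties and are equivariant", {
  expect_equal(normalized_ranks(c(10, 20, 30)), c(1/3, 2/3, 1))
  expect_equal(normalized_ranks(c(5, 5)), c(0.75, 0.75))
  set.seed(5)
  v <- rnorm(40)
  perm <- sample(40)
  expect_equal(normalized_ranks(v[perm]), normalized_ranks(v)[perm])
  expect_true(all(normalized_ranks(v) > 0 & normalized_ranks(v) <= 1))
  expect_error(normalized_ranks(numeric(0)), "value error.*empty")
})

test_that("Spearman concordance matches the direct d-squared formula", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)    # tie-free with prob. 1
    cc <- concordance_fitted(b, a)
    expect_equal(cc$spearman, spearman_d2(a, b), tolerance = 1e-12)
    expect_equal(cc$n_features, 30L)
    expect_true(all(cc$rank_pairs$reference > 0 & cc$rank_pairs$reference <= 1))
  }
})

test_that("constructed-value concordance hits the analytic extremes", {
  pm <- cbind(A = c(1, 5, 20, 80), B = c(2, 4, 30, 60))
  constructed <- 0.75 * pm[, 1] + 0.25 * pm[, 2]
  expect_equal(concordance_constructed(pm, constructed,
                                       c(A = 0.75, B = 0.25))$spearman, 1)
  expect_equal(concordance_constructed(pm, rev(constructed),
                                       c(A = 0.75, B = 0.25))$spearman, -1)
  expect_error(concordance_constructed(pm, constructed[1:3], c(A = 0.75, B = 0.25)),
               "value error.*equal length")

  # all-ties input is flagged, not silently NaN
  deg <- concordance_fitted(c(3, 3, 3, 3), c(1, 2, 3, 4))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$spearman))
})

test_that("noiseless synthetic TPM gives perfect constructed concordance", {
  tr <- titration_truth(n_features = 50, seed = 41, noise = 0)
  tpm <- counts_to_tpm(render_counts(tr))
  ev <- evaluate_unit(tpm, tr$design, "C")
  expect_equal(ev$concordance_constructed$spearman, 1, tolerance = 1e-12)
  expect_equal(ev$concordance_fitted$spearman, 1, tolerance = 1e-12)
})

test_that("ROC-like curves are empirical CDFs of absolute residuals", {
  r0 <- roc_like(rep(0, 10), thresholds = c(0, 0.5, 1))
  expect_equal(r0$proportions, c(1, 1, 1))

  r <- roc_like(c(0.1, -0.2, 0.3), thresholds = c(0.05, 0.15, 0.25, 0.35))
  expect_equal(r$proportions, c(0, 1/3, 2/3, 1))

  set.seed(13)
  x <- rnorm(200)
  rr <- roc_like(x)
  expect_equal(length(rr$thresholds), 101L)
  expect_true(all(diff(rr$proportions) >= 0))           # CDF monotone
  expect_equal(rr$proportions[101], 1)                   # reaches max |residual|
  ecdf_vals <- vapply(rr$thresholds, function(t) mean(abs(x) <= t), numeric(1))
  expect_equal(rr$proportions, ecdf_vals, tolerance = 1e-15)
  expect_true(rr$auc_like >= 0 && rr$auc_like <= 1)
  expect_error(roc_like(numeric(0)), "value error.*empty")
})

test_that("pooled thresholds put different units on one comparable axis", {
  small <- rnorm(100, sd = 0.1)
  large <- rnorm(100, sd = 10)
  grid <- pooled_thresholds(list(small, large))
  r_small <- roc_like(small, thresholds = grid)
  r_large <- roc_like(large, thresholds = grid)
  expect_identical(r_small$thresholds, r_large$thresholds)
  expect_gt(r_small$auc_like, r_large$auc_like)
})

test_that("distribution profiles detect the generator's modality", {
  tr2 <- titration_truth(n_features = 1000, seed = 43, bimodal_fraction = 0.5)
  prof2 <- distribution_profile(render_counts(tr2), transform = "log")
  expect_true(all(prof2$n_modes == 2L))

  tr1 <- titration_truth(n_features = 1000, seed = 43, bimodal_fraction = 0)
  prof1 <- distribution_profile(render_counts(tr1), transform = "log")
  expect_true(all(prof1$n_modes == 1L))

  # shared grid across samples
  expect_equal(ncol(prof2$density), 16L)
  expect_equal(length(prof2$grid), nrow(prof2$density))

  # constant column flagged degenerate
  v <- matrix(c(5, 5, 5, 1, 2, 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("S1", "S2")))
  prof <- distribution_profile(toy_matrix(v), transform = "identity")
  expect_true(prof$degenerate[["S1"]])
  expect_false(prof$degenerate[["S2"]])
})

test_that("log transformation degrades linearity relative to TPM", {
  tr <- titration_truth(n_features = 1000, seed = 47, noise = 0)
  cn <- render_counts(tr)
  tpm <- counts_to_tpm(cn)
  lg <- log_transform(cn)
  fit_tpm <- mixlin(tpm, tr$design, "C")
  fit_log <- mixlin(lg, tr$design, "C")
  grid <- pooled_thresholds(lapply(list(fit_tpm, fit_log), residuals))
  ev_tpm <- evaluate_unit(tpm, tr$design, "C", thresholds = grid)
  ev_log <- evaluate_unit(lg, tr$design, "C", thresholds = grid)
  expect_gt(abs(coef(fit_log)["(Intercept)"]), abs(coef(fit_tpm)["(Intercept)"]))
  expect_lt(ev_log$roc$auc_like, ev_tpm$roc$auc_like)
})

test_that("method summaries rank dominant units first and are deterministic", {
  sim <- simulate_titration(n_features = 400, seed = 51)
  tpm <- counts_to_tpm(sim$counts)
  design <- sim$truth$design
  grid <- pooled_thresholds(lapply(
    list(mixlin(tpm, design, "C"), mixlin(sim$counts, design, "C")), residuals))
  ev_tpm <- evaluate_unit(tpm, design, "C", thresholds = grid)
  ev_cnt <- evaluate_unit(sim$counts, design, "C", thresholds = grid)
  tab <- summarize_methods(list(ev_tpm, ev_cnt))
  expect_equal(tab$label[1], "TPM")     # depth-confounded counts rank below
  expect_lt(tab$mean_abs_bias[1], tab$mean_abs_bias[2])

  tab2 <- summarize_methods(list(ev_tpm, ev_tpm))
  expect_equal(tab2[1, -match(c("label", "rank"), names(tab2))],
               tab2[2, -match(c("label", "rank"), names(tab2))],
               ignore_attr = TRUE)

  ev_d <- evaluate_unit(tpm, design, "D")
  expect_error(summarize_methods(list(ev_tpm, ev_d)),
               "value error.*different mixture")
})
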