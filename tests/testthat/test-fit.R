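test_that("single-combination OLS recovers exact linear relationships", {
  A <- c(1, 2, 3, 4, 5); B <- c(5, 3, 1, 4, 2)
  X <- cbind(A = A, B = B)

  f <- fit_combination(A, X)                 # y is A itself
  expect_equal(unname(coef(f)), c(0, 1, 0), tolerance = 1e-9)

  f2 <- fit_combination(0.75 * A + 0.25 * B, X)
  expect_equal(unname(coef(f2)), c(0, 0.75, 0.25), tolerance = 1e-9)
  expect_equal(f2$residuals, rep(0, 5), tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)
  expect_equal(f2$residuals, (0.75 * A + 0.25 * B) - f2$fitted)
})

test_that("OLS agrees with the normal-equations oracle on perturbed data", {
  # A + B is constant here, so the intercept-free model is the identified one
  A <- c(1, 2, 3, 4); B <- c(4, 3, 2, 1)
  set.seed(1)
  y <- c(2, 2, 2, 2) + rnorm(4, sd = 0.01)
  f <- fit_combination(y, cbind(A = A, B = B), with_intercept = FALSE)
  expect_equal(unname(coef(f))[-1],
               ols_oracle(y, cbind(A, B), intercept = FALSE), tolerance = 1e-6)
  # with an intercept the same instance is collinear and must be refused
  expect_error(fit_combination(y, cbind(A = A, B = B)), "singularity")
})

test_that("OLS matches the oracle on randomized 10-feature instances", {
  set.seed(202)
  for (i in 1:30) {
    X <- cbind(A = rexp(10, 1 / 100), B = rexp(10, 1 / 100))
    y <- 0.6 * X[, 1] + 0.4 * X[, 2] + rnorm(10, sd = 5)
    f <- fit_combination(y, X)
    expect_equal(unname(coef(f)), ols_oracle(y, X), tolerance = 1e-6)
  }
})

test_that("degenerate regressions fail loudly", {
  A <- c(1, 2, 3, 4)
  expect_error(fit_combination(A, cbind(A = A, B = 2 * A)), "singularity")
  expect_error(fit_combination(A, cbind(A = A[1:3])), "value error.*same number")
  expect_error(fit_combination(A[1:3], cbind(A = A[1:3], B = c(4, 3, 2))),
               "data error.*fewer features")
})

test_that("aggregation over combinations is linear in the mixture columns", {
  tr <- equal_depth_truth(200, seed = 13)
  cn <- render_counts(tr)
  f <- mixlin(cn, tr$design, "C")
  expect_equal(f$n_combinations, 64L)

  # halving every C column halves both coefficients (OLS linearity in y)
  half <- cn
  c_cols <- half$sample_meta$sample_type == "C"
  half$values[, c_cols] <- half$values[, c_cols] * 0.5
  fh <- mixlin(half, tr$design, "C")
  expect_equal(unname(coef(fh)[c("A", "B")]), c(0.375, 0.125), tolerance = 1e-9)

  d2 <- titration_design(2)
  tr2 <- equal_depth_truth(100, seed = 14, design = d2)
  f2 <- mixlin(render_counts(tr2), d2, "C")
  expect_equal(f2$n_combinations, 8L)
})

test_that("aggregate means equal the average over per-combination fits", {
  tr <- titration_truth(n_features = 120, seed = 17, noise = 0.05,
                        design = titration_design(2))
  cn <- render_counts(tr)
  f <- mixlin(cn, tr$design, "C")

  combos <- enumerate_combinations(tr$design, "C")
  col <- function(ty, r) cn$values[f$feature_ids, paste(ty, r, sep = "_")]
  fits <- lapply(seq_len(nrow(combos)), function(i) {
    fit_combination(col("C", combos$C[i]),
                    cbind(A = col("A", combos$A[i]), B = col("B", combos$B[i])))
  })
  expect_equal(unname(coef(f)),
               unname(rowMeans(vapply(fits, coef, numeric(3)))),
               tolerance = 1e-12)
  expect_equal(unname(residuals(f)),
               unname(rowMeans(vapply(fits, `[[`, numeric(length(f$feature_ids)),
                                      "residuals"))),
               tolerance = 1e-12)
  expect_equal(unname(fitted(f)),
               unname(rowMeans(vapply(fits, `[[`, numeric(length(f$feature_ids)),
                                      "fitted"))),
               tolerance = 1e-12)
  # percentile interval brackets the per-combination estimates
  expect_true(all(f$ci_percentile["2.5%", ] <= f$coefficients))
  expect_true(all(f$ci_percentile["97.5%", ] >= f$coefficients))
})

test_that("feature order does not influence the fit", {
  tr <- titration_truth(n_features = 90, seed = 19, noise = 0.05,
                        design = titration_design(2))
  cn <- render_counts(tr)
  f1 <- mixlin(cn, tr$design, "C")
  set.seed(1)
  perm <- sample(seq_len(nrow(cn$values)))
  cp <- cn
  cp$values <- cn$values[perm, , drop = FALSE]
  f2 <- mixlin(cp, tr$design, "C")
  expect_equal(coef(f2), coef(f1), tolerance = 1e-12)
  expect_equal(residuals(f2)[f1$feature_ids], residuals(f1), tolerance = 1e-12)
})

test_that("all-zero features are dropped once, identically for all models", {
  tr <- equal_depth_truth(60, seed = 23)
  cn <- render_counts(tr)
  cn$values[c(3, 7), ] <- 0
  f <- mixlin(cn, tr$design, "C")
  expect_equal(f$n_dropped, 2L)
  expect_false(any(rownames(cn$values)[c(3, 7)] %in% f$feature_ids))
  f_none <- mixlin(cn, tr$design, "C", filter = "none")
  expect_equal(f_none$n_dropped, 0L)
})

test_that("noisy TPM recovery matches the errors-in-variables prediction", {
  # noiseless: exact recovery no matter the depth structure
  tr0 <- titration_truth(n_features = 400, seed = 31, noise = 0)
  f0 <- mixlin(counts_to_tpm(render_counts(tr0)), tr0$design, "C")
  expect_equal(unname(coef(f0)[c("A", "B")]), c(0.75, 0.25), tolerance = 1e-9)

  # noisy replicates attenuate the coefficients; the EIV oracle predicts how much
  for (disp in c(0.05, 0.1)) {
    diffs <- vapply(1:4, function(s) {
      tr <- titration_truth(n_features = 800, seed = 300 + s, noise = disp)
      f <- mixlin(counts_to_tpm(render_counts(tr)), tr$design, "C")
      pred <- eiv_attenuated_coef(tr, "C", disp)
      unname(coef(f)["A"]) - pred[1]
    }, numeric(1))
    # mean deviation from the prediction within 3 MC standard errors (+ the
    # delta-method approximation slack)
    expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / 2 + 0.01)
    # attenuation direction: estimates do not exceed the design weight
    trx <- titration_truth(n_features = 800, seed = 301, noise = disp)
    fx <- mixlin(counts_to_tpm(render_counts(trx)), trx$design, "C")
    expect_lt(unname(coef(fx)["A"]), 0.75)
  }
})

test_that("rescaled fits standardize exactly and inherit exact fits", {
  set.seed(7)
  A <- rexp(50, 1 / 100); B <- rexp(50, 1 / 100)
  y <- 0.75 * A + 0.25 * B
  rf <- fit_rescaled(y, cbind(A = A, B = B))
  expect_equal(rf$residuals, rep(0, 50), tolerance = 1e-9)

  yn <- y + rnorm(50, sd = 3)
  rfn <- fit_rescaled(yn, cbind(A = A, B = B))
  raw <- fit_combination(yn, cbind(A = A, B = B))
  # standardized slopes = raw slopes * sd(x)/sd(y)
  expect_equal(unname(rfn$coefficients["A"]),
               unname(raw$coefficients["A"]) * sd(A) / sd(yn), tolerance = 1e-9)
  expect_equal(unname(rfn$coefficients["B"]),
               unname(raw$coefficients["B"]) * sd(B) / sd(yn), tolerance = 1e-9)
  expect_equal(unname(rfn$intercept), 0, tolerance = 1e-9)

  expect_error(fit_rescaled(yn, cbind(A = A, B = rep(2, 50))),
               "value error.*zero variance")
})

test_that("mixlin methods expose the aggregate fit coherently", {
  tr <- equal_depth_truth(150, seed = 37)
  cn <- render_counts(tr)
  f <- mixlin(cn, tr$design, "C")
  s <- summary(f)
  expect_s3_class(s, "summary.mixlin")
  expect_equal(s$coefficients["A", "expected"], 0.75)
  expect_equal(s$coefficients["A", "bias"], 0, tolerance = 1e-9)

  ci <- confint(f)
  expect_equal(dim(ci), c(3L, 2L))
  expect_true(all(ci[, 1] <= ci[, 2]))
  cin <- confint(f, type = "normal")
  expect_true(all(cin[, 1] <= cin[, 2]))

  expect_equal(predict(f), fitted(f))
  nd <- cbind(A = c(100, 200), B = c(50, 10))
  expect_equal(unname(predict(f, nd)),
               unname(nd %*% c(0.75, 0.25))[, 1] + unname(coef(f)["(Intercept)"]),
               tolerance = 1e-9)

  expect_output(print(f), "Mixture linearity fit")
  expect_output(print(s), "64 models")
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(f); grDevices::dev.off()
  expect_true(file.exists(path))

  expect_error(mixlin(cn, tr$design, "Z"), "design error.*unknown")
  tiny <- titration_design(1)
  expect_error(mixlin(cn, tiny, "C"), NA)  # fewer replicates than present is fine
})
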