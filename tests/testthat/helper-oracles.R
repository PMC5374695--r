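# Independent oracles, kept free of the code paths they check.

# OLS via explicit normal equations (implementation uses QR through lm.fit)
ols_oracle <- function(y, X, intercept = TRUE) {
  M <- if (intercept) cbind(1, X) else X
  beta <- solve(t(M) %*% M, t(M) %*% y)
  as.numeric(beta)
}

# Spearman via the direct sum-of-squared-rank-differences formula (tie-free)
spearman_d2 <- function(a, b) {
  n <- length(a)
  d <- rank(a) - rank(b)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# equal-depth noiseless truth: every sample at the same expected library size
equal_depth_truth <- function(n_features, seed, noise = 0, depth = 8e6,
                              design = titration_design()) {
  ids <- unlist(lapply(names(design$replicates), function(ty) {
    paste(ty, seq_len(design$replicates[[ty]]), sep = "_")
  }))
  titration_truth(n_features = n_features, design = design, seed = seed,
                  noise = noise,
                  library_sizes = stats::setNames(rep(depth, length(ids)), ids))
}

# Errors-in-variables prediction of the attenuated mixing coefficients when
# noisy pure replicates stand on the regression's right-hand side: with
# signal covariance S (expected TPM of the pure sources across features) and
# mean measurement-noise variances N (delta method from the NB count noise,
# denominator held fixed), plim(beta_hat) = (S + N)^-1 S beta.
eiv_attenuated_coef <- function(truth, mixture, disp) {
  tA <- 1e6 * truth$base_expr_A
  tB <- 1e6 * truth$base_expr_B
  L <- truth$feature_lengths
  w <- truth$proportions[[mixture]]
  noise_var <- function(p, lib) {
    S <- sum(p * L)
    mu <- lib * p * L / S
    (1e6 * S / (lib * L))^2 * (mu + disp * mu^2)
  }
  libs <- truth$library_sizes
  nv <- c(mean(noise_var(truth$base_expr_A,
                         mean(libs[grepl("^A_", names(libs))]))),
          mean(noise_var(truth$base_expr_B,
                         mean(libs[grepl("^B_", names(libs))]))))
  S2 <- stats::cov(cbind(tA, tB))
  drop(solve(S2 + diag(nv)) %*% S2 %*% c(w[["A"]], w[["B"]]))
}

# tiny deterministic quant_matrix for io/unit tests
toy_matrix <- function(values, unit = "count") {
  sm <- data.frame(sample_id = colnames(values),
                   sample_type = colnames(values),
                   replicate = 1L,
                   library_size = colSums(values))
  quant_matrix(values, sm, unit = unit)
}
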