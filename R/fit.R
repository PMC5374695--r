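## The mixture regression.  One "combination" regresses one mixture replicate
## on one replicate of each pure sample across features (observations =
## features); the full analysis fits every replicate combination and averages
## coefficients, fitted values and residuals over combinations.

#' Fit one replicate combination by ordinary least squares
#'
#' Regresses a mixture replicate's per-feature abundances on one replicate of
#' each pure sample: `y ~ intercept + X %*% coefficients`, solved by QR least
#' squares across features.  In a unit that mixes linearly the coefficients
#' recover the physical mixing weights and the intercept is zero.
#'
#' @param y numeric vector of mixture abundances (one value per feature).
#' @param X numeric matrix with one column per pure sample type, rows aligned
#'   with `y`.
#' @param with_intercept estimate the intercept (default) or force it to zero.
#' @return An object of class `"combination_fit"`: `coefficients` (named by
#'   pure type), `intercept`, `se` (standard errors, intercept first),
#'   `fitted`, `residuals`, `r_squared`, `n`.
#' @examples
#' A <- c(1, 2, 3, 4); B <- c(4, 3, 2, 1)
#' fit <- fit_combination(0.75 * A + 0.25 * B, cbind(A = A, B = B))
#' coef(fit)
#' @export
fit_combination <- function(y, X, with_intercept = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("value error: y and X must have the same number of features", call. = FALSE)
  }
  p <- ncol(X) + as.integer(with_intercept)
  if (length(y) < p + 1L) {
    stop("data error: fewer features than parameters + 1", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  M <- if (with_intercept) cbind(`(Intercept)` = 1, X) else X
  if (qr(M)$rank < ncol(M)) {
    stop("singularity error: collinear predictors in mixture regression",
         call. = FALSE)
  }
  fit <- lm.fit(M, y)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  centred <- if (with_intercept) y - mean(y) else y
  tss <- sum(centred^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  sigma2 <- rss / (length(y) - ncol(M))
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- names(cf)
  structure(
    list(coefficients = cf[colnames(X)],
         intercept = if (with_intercept) unname(cf["(Intercept)"]) else 0,
         se = se,
         fitted = fit$fitted.values,
         residuals = fit$residuals,
         r_squared = r2,
         n = length(y)),
    class = "combination_fit"
  )
}

#' @export
coef.combination_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.combination_fit <- function(x, ...) {
  cat("Mixture combination fit (", x$n, " features)\n", sep = "")
  print(round(coef(x), 6))
  cat("R-squared:", format(x$r_squared, digits = 6), "\n")
  invisible(x)
}

#' Fit the rescaled mixture model
#'
#' Standardizes every variable by its own across-feature mean and standard
#' deviation before the least-squares fit, making residual magnitudes
#' comparable across quantification units with different ranges.  The
#' standardized coefficients equal the raw coefficients scaled by
#' `sd(x)/sd(y)`.
#'
#' @inheritParams fit_combination
#' @return A `"combination_fit"` with additional class `"rescaled_fit"`;
#'   `scaling` records the centers and scales used.
#' @export
fit_rescaled <- function(y, X, with_intercept = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  sds <- c(sd(y), apply(X, 2L, sd))
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("value error: zero variance in a variable; rescaled model undefined",
         call. = FALSE)
  }
  ys <- (y - mean(y)) / sd(y)
  Xs <- scale(X)
  fit <- fit_combination(ys, Xs, with_intercept = with_intercept)
  fit$scaling <- list(center = c(y = mean(y), colMeans(X)),
                      scale = setNames(sds, c("y", colnames(X))))
  class(fit) <- c("rescaled_fit", class(fit))
  fit
}

#' Evaluate mixture linearity over all replicate combinations
#'
#' The central fitting function.  For a declared mixture type it enumerates
#' every combination of one replicate per involved sample type
#' ([enumerate_combinations()]), fits the mixture regression for each
#' ([fit_combination()]), and aggregates: coefficient means with empirical
#' 2.5/97.5 percentile intervals across combinations, and per-feature means
#' of fitted values and residuals.  Features that are zero in every involved
#' sample are dropped once, before any fit, so all combinations see the same
#' feature set.
#'
#' @param x a [quant_matrix()] containing all replicates the design declares.
#' @param design a [mixture_design()].
#' @param mixture mixture type to model (e.g. `"C"`).
#' @param with_intercept estimate the intercept (default) or force zero.
#' @param filter `"drop_all_zero"` (default) or `"none"`.
#' @return An object of class `"mixlin"` supporting `print`, `summary`,
#'   `coef`, `confint`, `fitted`, `residuals`, `predict` and `plot`.
#' @examples
#' sim <- simulate_titration(n_features = 300, seed = 1)
#' fit <- mixlin(counts_to_tpm(sim$counts), sim$truth$design, mixture = "C")
#' coef(fit)
#' summary(fit)
#' @export
mixlin <- function(x, design, mixture = "C", with_intercept = TRUE,
                   filter = c("drop_all_zero", "none")) {
  stopifnot(inherits(x, "quant_matrix"), inherits(design, "mixture_design"))
  filter <- match.arg(filter)
  if (!mixture %in% names(design$mixtures)) {
    stop(sprintf("design error: unknown mixture type '%s'", mixture), call. = FALSE)
  }
  check_matrix_design(x, design)
  combos <- enumerate_combinations(design, mixture)
  types <- names(combos)

  col_of <- function(ty, rep) {
    idx <- which(x$sample_meta$sample_type == ty & x$sample_meta$replicate == rep)
    if (length(idx) != 1L) {
      stop(sprintf("data error: expected exactly one sample for %s replicate %d",
                   ty, rep), call. = FALSE)
    }
    idx
  }
  involved_cols <- unlist(lapply(types, function(ty) {
    which(x$sample_meta$sample_type == ty)
  }))
  keep <- rep(TRUE, nrow(x$values))
  if (filter == "drop_all_zero") {
    keep <- rowSums(x$values[, involved_cols, drop = FALSE] != 0) > 0
  }
  vals <- x$values[keep, , drop = FALSE]
  n_par <- length(design$pure) + as.integer(with_intercept)
  if (nrow(vals) < n_par + 1L) {
    stop("data error: fewer features than parameters after filtering", call. = FALSE)
  }

  n_comb <- nrow(combos)
  coef_samples <- matrix(NA_real_, n_comb, 1L + length(design$pure),
                         dimnames = list(NULL, c("(Intercept)", design$pure)))
  se_samples <- coef_samples
  r2 <- numeric(n_comb)
  fitted_sum <- numeric(nrow(vals))
  resid_sum <- numeric(nrow(vals))
  for (i in seq_len(n_comb)) {
    Xi <- vapply(design$pure, function(ty) {
      vals[, col_of(ty, combos[i, ty])]
    }, numeric(nrow(vals)))
    yi <- vals[, col_of(mixture, combos[i, mixture])]
    fit <- fit_combination(yi, Xi, with_intercept = with_intercept)
    coef_samples[i, ] <- coef(fit)
    se_samples[i, names(fit$se)] <- fit$se
    r2[i] <- fit$r_squared
    fitted_sum <- fitted_sum + fit$fitted
    resid_sum <- resid_sum + fit$residuals
  }

  ci <- apply(coef_samples, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("2.5%", "97.5%")
  expected <- c(0, design$mixtures[[mixture]])
  names(expected) <- colnames(coef_samples)

  structure(
    list(call = match.call(),
         design = design, mixture = mixture, unit = x$unit, level = x$level,
         with_intercept = with_intercept,
         combinations = combos, n_combinations = n_comb,
         coef_samples = coef_samples, se_samples = se_samples,
         coefficients = colMeans(coef_samples),
         ci_percentile = ci,
         expected = expected,
         r_squared = r2,
         feature_ids = rownames(vals),
         n_features = nrow(vals),
         n_dropped = sum(!keep),
         mean_fitted = setNames(fitted_sum / n_comb, rownames(vals)),
         mean_residuals = setNames(resid_sum / n_comb, rownames(vals)),
         mixture_mean = rowMeans(vals[, involved_cols[
           x$sample_meta$sample_type[involved_cols] == mixture], drop = FALSE]),
         pure_means = vapply(design$pure, function(ty) {
           rowMeans(vals[, which(x$sample_meta$sample_type == ty), drop = FALSE])
         }, numeric(nrow(vals)))),
    class = "mixlin"
  )
}

#' @export
print.mixlin <- function(x, digits = 6, ...) {
  cat(sprintf("Mixture linearity fit: %s ~ %s  [unit %s, %d features, %d models]\n",
              x$mixture,
              paste(x$design$pure, collapse = " + "),
              x$unit, x$n_features, x$n_combinations))
  cat("Mean coefficients across models:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.mixlin <- function(object, ...) object$coefficients

#' @export
fitted.mixlin <- function(object, ...) object$mean_fitted

#' @export
residuals.mixlin <- function(object, ...) object$mean_residuals

#' @param parm coefficients to report (names or indices); defaults to all.
#' @param level confidence level.
#' @param type `"percentile"` for empirical percentile intervals across the
#'   replicate combinations (the headline interval), `"normal"` for the mean
#'   per-fit standard-error interval.
#' @rdname mixlin
#' @export
confint.mixlin <- function(object, parm, level = 0.95,
                           type = c("percentile", "normal"), ...) {
  type <- match.arg(type)
  a <- (1 - level) / 2
  if (type == "percentile") {
    ci <- t(apply(object$coef_samples, 2L, quantile, probs = c(a, 1 - a),
                  names = FALSE))
  } else {
    z <- stats::qnorm(1 - a)
    mean_se <- colMeans(object$se_samples)
    ci <- cbind(object$coefficients - z * mean_se,
                object$coefficients + z * mean_se)
  }
  colnames(ci) <- sprintf("%.1f%%", 100 * c(a, 1 - a))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @param newdata optional matrix or data frame with one column per pure type
#'   (new pure-sample profiles); defaults to the per-combination-averaged
#'   fitted values of the training data.
#' @rdname mixlin
#' @export
predict.mixlin <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$mean_fitted)
  newdata <- as.matrix(newdata)
  if (!all(object$design$pure %in% colnames(newdata))) {
    stop("value error: newdata must have one column per pure type", call. = FALSE)
  }
  drop(newdata[, object$design$pure, drop = FALSE] %*%
         object$coefficients[object$design$pure]) +
    object$coefficients["(Intercept)"]
}

#' @export
summary.mixlin <- function(object, ...) {
  tab <- data.frame(
    expected = object$expected,
    mean = object$coefficients,
    bias = object$coefficients - object$expected,
    sd = apply(object$coef_samples, 2L, sd),
    `2.5%` = object$ci_percentile["2.5%", ],
    `97.5%` = object$ci_percentile["97.5%", ],
    check.names = FALSE
  )
  structure(
    list(coefficients = tab, mixture = object$mixture, unit = object$unit,
         n_combinations = object$n_combinations,
         n_features = object$n_features, n_dropped = object$n_dropped,
         mean_r_squared = mean(object$r_squared)),
    class = "summary.mixlin"
  )
}

#' @export
print.summary.mixlin <- function(x, digits = 6, ...) {
  cat(sprintf("Mixture linearity of '%s' in unit %s\n", x$mixture, x$unit))
  cat(sprintf("%d models over replicate combinations; %d features (%d dropped as all-zero)\n",
              x$n_combinations, x$n_features, x$n_dropped))
  print(round(x$coefficients, digits))
  cat("Mean R-squared:", format(x$mean_r_squared, digits = digits), "\n")
  invisible(x)
}

#' @param which which panels to draw: 1 = per-combination coefficient
#'   estimates (jittered points over boxes, expected values as red lines),
#'   2 = averaged residuals against averaged fitted values.
#' @param ... further arguments passed to plotting primitives.
#' @rdname mixlin
#' @export
plot.mixlin <- function(x, which = 1:2, ...) {
  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  par(mfrow = c(1, length(which)))
  if (1 %in% which) {
    cs <- x$coef_samples
    boxplot(cs, outline = FALSE, ylim = range(cs),
            main = sprintf("Coefficients over %d models (%s)",
                           x$n_combinations, x$unit),
            ylab = "estimate")
    for (j in seq_len(ncol(cs))) {
      points(jitter(rep(j, nrow(cs)), amount = 0.15), cs[, j],
             pch = 16, cex = 0.6, col = "grey40")
      lines(c(j - 0.4, j + 0.4), rep(x$expected[j], 2), col = "red", lwd = 2)
    }
  }
  if (2 %in% which) {
    plot(x$mean_fitted, x$mean_residuals, pch = 16, cex = 0.5,
         xlab = "mean fitted", ylab = "mean residual",
         main = sprintf("Residuals (%s)", x$unit))
    abline(h = 0, col = "red")
  }
  invisible(x)
}
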