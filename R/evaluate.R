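## Model-assessment statistics: rank concordance, ROC-like residual curves,
## distribution profiling, and the cross-unit summary table.

#' Normalized ranks
#'
#' Ascending ranks with ties averaged, divided by the vector length, so ranks
#' lie in (0, 1] and are comparable across feature sets of different sizes.
#'
#' @param v numeric vector, length >= 1.
#' @return Numeric vector of normalized ranks.
#' @examples
#' normalized_ranks(c(10, 20, 30))  # 1/3 2/3 1
#' @export
normalized_ranks <- function(v) {
  if (length(v) == 0L) stop("value error: empty input", call. = FALSE)
  rank(v, ties.method = "average") / length(v)
}

new_concordance <- function(reference, comparison) {
  if (length(reference) != length(comparison)) {
    stop("value error: vectors must have equal length", call. = FALSE)
  }
  if (length(reference) == 0L) stop("value error: empty input", call. = FALSE)
  degenerate <- sd(reference) == 0 || sd(comparison) == 0
  rank_pairs <- data.frame(reference = normalized_ranks(reference),
                           comparison = normalized_ranks(comparison))
  rho <- if (degenerate) NA_real_ else
    cor(reference, comparison, method = "spearman")
  structure(
    list(rank_pairs = rank_pairs, spearman = rho,
         n_features = length(reference), degenerate = degenerate),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Rank concordance over %d features: degenerate (all ties)\n",
                x$n_features))
  } else {
    cat(sprintf("Rank concordance over %d features: Spearman rho = %.6f\n",
                x$n_features, x$spearman))
  }
  invisible(x)
}

#' Concordance of a mixture against its constructed value
#'
#' Compares the measured mixture profile (replicate mean) against the value
#' constructed from the pure-sample replicate means with the physical mixing
#' weights (e.g. `0.75*mean(A) + 0.25*mean(B)`), on normalized ranks, with
#' Spearman's rho as the scalar summary.  Under linear mixing the two agree
#' perfectly.
#'
#' @param pure_means matrix with one column per pure type (replicate means per
#'   feature) or a named list of vectors.
#' @param mixture_mean per-feature replicate mean of the mixture sample.
#' @param weights named mixing weights over the pure types.
#' @return An object of class `"concordance"`: `rank_pairs`, `spearman`,
#'   `n_features`, `degenerate`.
#' @export
concordance_constructed <- function(pure_means, mixture_mean, weights) {
  pure_means <- as.matrix(as.data.frame(pure_means))
  if (!all(names(weights) %in% colnames(pure_means))) {
    stop("value error: weights must be named by pure types of pure_means",
         call. = FALSE)
  }
  constructed <- drop(pure_means[, names(weights), drop = FALSE] %*%
                        as.numeric(weights))
  new_concordance(constructed, as.numeric(mixture_mean))
}

#' Concordance of a mixture against model-fitted values
#'
#' As [concordance_constructed()], but the reference is the per-feature
#' average of fitted values over all replicate combinations.
#'
#' @param mixture_mean per-feature replicate mean of the mixture sample.
#' @param mean_fitted per-feature combination-averaged fitted values (e.g.
#'   `fitted(mixlin_fit)`).
#' @return An object of class `"concordance"`; an all-ties input yields a
#'   result flagged `degenerate` with `spearman = NA` rather than silent NaN.
#' @export
concordance_fitted <- function(mixture_mean, mean_fitted) {
  new_concordance(as.numeric(mean_fitted), as.numeric(mixture_mean))
}

#' ROC-like curve over absolute residuals
#'
#' Traces the proportion of features whose absolute residual is at most t
#' over a grid of thresholds t.  By default the grid is the 101 evenly spaced
#' quantiles (0 to 1) of the pooled absolute residuals, so curves from
#' different units can share one axis; pass the pooled grid explicitly via
#' `thresholds` when comparing units (see [pooled_thresholds()]).  `auc_like`
#' is the mean proportion over the grid — a normalized area in `[0, 1]`,
#' higher = tighter residuals.
#'
#' @param residuals numeric vector of residuals (signs ignored).
#' @param thresholds optional increasing non-negative threshold grid.
#' @param n_grid grid size when `thresholds` is omitted.
#' @return An object of class `"roc_like"`: `thresholds`, `proportions`,
#'   `auc_like`, `n_features`.
#' @export
roc_like <- function(residuals, thresholds = NULL, n_grid = 101L) {
  if (length(residuals) == 0L) stop("value error: empty residuals", call. = FALSE)
  if (any(!is.finite(residuals))) {
    stop("value error: residuals must be finite", call. = FALSE)
  }
  ar <- abs(as.numeric(residuals))
  if (is.null(thresholds)) {
    thresholds <- quantile(ar, probs = seq(0, 1, length.out = n_grid),
                           names = FALSE)
  }
  thresholds <- sort(as.numeric(thresholds))
  if (any(thresholds < 0)) {
    stop("value error: thresholds must be non-negative", call. = FALSE)
  }
  props <- vapply(thresholds, function(t) mean(ar <= t), numeric(1))
  structure(
    list(thresholds = thresholds, proportions = props,
         auc_like = mean(props), n_features = length(ar)),
    class = "roc_like"
  )
}

#' @export
print.roc_like <- function(x, ...) {
  cat(sprintf("ROC-like residual curve: %d features, %d thresholds, auc_like = %.4f\n",
              x$n_features, length(x$thresholds), x$auc_like))
  invisible(x)
}

#' Pooled threshold grid for comparable ROC-like curves
#'
#' Evenly spaced quantiles of the pooled absolute residuals of several fits,
#' so that each unit's curve is evaluated on the same axis.
#'
#' @param residual_list list of residual vectors (one per unit under
#'   comparison).
#' @param n_grid number of grid points.
#' @return Increasing numeric vector of thresholds.
#' @export
pooled_thresholds <- function(residual_list, n_grid = 101L) {
  pooled <- abs(unlist(residual_list, use.names = FALSE))
  if (length(pooled) == 0L) stop("value error: empty residuals", call. = FALSE)
  quantile(pooled, probs = seq(0, 1, length.out = n_grid), names = FALSE)
}

#' Per-sample distribution profiles
#'
#' Kernel-density profiles of each sample's abundances on a shared grid (so
#' samples and units are directly comparable), with a simple mode count:
#' local density maxima whose height exceeds a prominence fraction of the
#' sample's maximum density.  Bulk expression profiles typically show one or
#' two peaks on the log scale; the mode count makes that observation
#' testable.
#'
#' @param m a [quant_matrix()].
#' @param transform `"log"` profiles `log2(x + 1)` (the usual view for
#'   linear-scale units), `"identity"` profiles raw values.
#' @param n_grid number of shared grid points.
#' @param prominence minimum mode height as a fraction of the per-sample
#'   maximum density.
#' @return An object of class `"distribution_profile"`: shared `grid`,
#'   `density` matrix (grid x samples), per-sample `n_modes`, and a
#'   `degenerate` flag per sample (constant column).
#' @export
distribution_profile <- function(m, transform = c("log", "identity"),
                                 n_grid = 512L, prominence = 0.1) {
  stopifnot(inherits(m, "quant_matrix"))
  transform <- match.arg(transform)
  vals <- m$values
  if (transform == "log") {
    if (any(vals < 0)) stop("value error: log profile requires non-negative values",
                            call. = FALSE)
    vals <- log2(vals + 1)
  }
  rng <- range(vals)
  degenerate <- apply(vals, 2L, function(col) sd(col) == 0)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  dens <- matrix(0, n_grid, ncol(vals), dimnames = list(NULL, colnames(vals)))
  n_modes <- setNames(integer(ncol(vals)), colnames(vals))
  for (j in seq_len(ncol(vals))) {
    if (degenerate[j]) { n_modes[j] <- 1L; next }
    d <- density(vals[, j], from = rng[1], to = rng[2], n = n_grid)
    dens[, j] <- d$y
    n_modes[j] <- count_modes(d$y, prominence)
  }
  structure(
    list(grid = grid, density = dens, n_modes = n_modes,
         degenerate = degenerate, transform = transform,
         unit = m$unit),
    class = "distribution_profile"
  )
}

## local maxima above `prominence` * max(y)
count_modes <- function(y, prominence) {
  thr <- prominence * max(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(peaks) == 0L) return(1L)
  sum(y[peaks] >= thr)
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat(sprintf("Distribution profile (%s scale, unit %s): %d samples\n",
              x$transform, x$unit, ncol(x$density)))
  cat("  modes per sample: ", paste(x$n_modes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Run the full assessment battery for one quantification unit
#'
#' Fits the mixture regression over all replicate combinations
#' ([mixlin()]), then computes constructed-value and fitted-value rank
#' concordance, the ROC-like residual curve, and the rescaled-model fit (on
#' replicate-mean profiles).
#'
#' @param m a [quant_matrix()].
#' @param design a [mixture_design()].
#' @param mixture mixture type to evaluate.
#' @param thresholds optional shared threshold grid for the ROC-like curve.
#' @param label label for reporting; defaults to the matrix unit.
#' @return An object of class `"unit_evaluation"` bundling `fit`,
#'   `concordance_constructed`, `concordance_fitted`, `roc`, `rescaled`.
#' @export
evaluate_unit <- function(m, design, mixture = "C", thresholds = NULL,
                          label = m$unit) {
  fit <- mixlin(m, design, mixture = mixture)
  conc_c <- concordance_constructed(fit$pure_means, fit$mixture_mean,
                                    design$mixtures[[mixture]])
  conc_f <- concordance_fitted(fit$mixture_mean, fit$mean_fitted)
  roc <- roc_like(fit$mean_residuals, thresholds = thresholds)
  rescaled <- fit_rescaled(fit$mixture_mean, fit$pure_means)
  structure(
    list(label = label, mixture = mixture, fit = fit,
         concordance_constructed = conc_c,
         concordance_fitted = conc_f,
         roc = roc, rescaled = rescaled),
    class = "unit_evaluation"
  )
}

#' @export
print.unit_evaluation <- function(x, ...) {
  cat(sprintf("Unit evaluation '%s' (mixture %s)\n", x$label, x$mixture))
  print(x$fit)
  print(x$concordance_constructed)
  print(x$roc)
  invisible(x)
}

#' Summarize and rank quantification units
#'
#' Builds one row per evaluated unit: coefficient bias against the design
#' weights, intercept magnitude, percentile-interval widths, both Spearman
#' concordances, the ROC-like area, and the rescaled-model residual RMS.
#' Because different units live on very different numeric scales, the
#' intercept used for comparison (`abs_intercept`) is standardized by the
#' across-feature standard deviation of the measured mixture profile —
#' offset per unit of spread; the raw value is kept in
#' `abs_intercept_raw`.  Rows are ordered by (mean absolute coefficient bias
#' ascending, standardized absolute intercept ascending, `auc_like`
#' descending) — a convenience composite for reporting, not a formal score.
#'
#' @param evaluations list of `"unit_evaluation"` objects (same design and
#'   mixture type).
#' @return A data frame, one row per unit, best first.
#' @export
summarize_methods <- function(evaluations) {
  stopifnot(length(evaluations) >= 1L,
            all(vapply(evaluations, inherits, logical(1), "unit_evaluation")))
  mixtures <- vapply(evaluations, function(e) e$mixture, character(1))
  if (length(unique(mixtures)) != 1L) {
    stop("value error: evaluations cover different mixture types", call. = FALSE)
  }
  pure <- evaluations[[1L]]$fit$design$pure
  rows <- lapply(evaluations, function(e) {
    fit <- e$fit
    bias <- fit$coefficients[pure] - fit$expected[pure]
    widths <- fit$ci_percentile["97.5%", ] - fit$ci_percentile["2.5%", ]
    row <- data.frame(label = e$label, stringsAsFactors = FALSE)
    for (ty in pure) row[[paste0("bias_", ty)]] <- unname(bias[ty])
    row$abs_intercept_raw <- abs(unname(fit$coefficients["(Intercept)"]))
    row$abs_intercept <- row$abs_intercept_raw / sd(fit$mixture_mean)
    row$mean_abs_bias <- mean(abs(bias))
    for (ty in pure) row[[paste0("ci_width_", ty)]] <- unname(widths[ty])
    row$ci_width_intercept <- unname(widths["(Intercept)"])
    row$spearman_constructed <- e$concordance_constructed$spearman
    row$spearman_fitted <- e$concordance_fitted$spearman
    row$auc_like <- e$roc$auc_like
    row$rescaled_rms <- sqrt(mean(e$rescaled$residuals^2))
    row
  })
  tab <- do.call(rbind, rows)
  if (any(!is.finite(as.matrix(tab[, -1L])))) {
    warning("non-finite entries in method summary (degenerate concordance?)")
  }
  ord <- order(tab$mean_abs_bias, tab$abs_intercept, -tab$auc_like)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
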