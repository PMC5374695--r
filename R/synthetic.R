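## Synthetic titration experiments with known ground truth.
##
## The generator works on molecule proportions: each pure sample is a
## probability vector over features, a mixture is the convex combination of
## the pure vectors with the declared weights, and sequencing turns molecule
## proportions into fragment counts by length weighting:
##   E[count_i] = library_size * p_i * L_i / sum_j(p_j * L_j).
## This makes TPM exactly linear in the mixing weights while raw counts are
## confounded by library size -- the qualitative behaviour titration
## benchmarks observe on real data.

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Generate the ground truth of a synthetic titration experiment
#'
#' Draws per-feature molecule abundances for two pure RNA sources A and B from
#' a two-component log-normal mixture (two sharp peaks on the log scale, as
#' bulk expression profiles typically show), plus feature lengths and
#' per-sample library sizes.  Mixture samples are convex combinations of the
#' pure molecule-proportion vectors with the declared weights.
#'
#' The two pure sources are calibrated to the same length-weighted normalizer
#' `sum(p_i * L_i)` (a common mean fragment length), so that mixing molecules
#' and mixing sequenced mass coincide: a mixture's count column at equal
#' sequencing depth is then exactly the weighted sum of the pure count
#' columns, and its TPM column is exactly the weighted sum of the pure TPM
#' columns, at the declared weights.  The calibration is an affine-in-length
#' tilt of B's proportions (two constraints: proportions still sum to one and
#' the mean fragment length matches A's); at realistic scales it perturbs
#' each proportion by well under one percent.
#'
#' Default library sizes reproduce the canonical benchmark's depth structure:
#' every sample at `base_depth` except replicates 1, 3 and 4 of pure sample A,
#' which are sequenced at twice the depth, so that A replicate 2 is the only A
#' replicate depth-matched to the B and mixture samples.
#'
#' @param n_features number of features (genes or isoforms), >= 2.
#' @param design a [mixture_design()] naming pure types `A` and `B`.
#' @param library_sizes named numeric vector of expected fragment totals, one
#'   per sample id (`"A_1"`, ..., `"D_4"`); `NULL` for the default depth
#'   structure described above.
#' @param base_depth base expected library size used when `library_sizes` is
#'   `NULL`.
#' @param noise negative-binomial dispersion of replicate counts (0 =
#'   noiseless, deterministic rendering).
#' @param bimodal_fraction fraction of features whose abundance is drawn from
#'   the low-expression mode, in `[0, 1]`.
#' @param low_meanlog,high_meanlog,sdlog natural-log means of the low and high
#'   expression modes and their common log-sd.
#' @param length_meanlog,length_sdlog log-normal parameters of feature lengths
#'   (bases); lengths are rounded and floored at 200.
#' @param depth_jitter_sd log-sd of multiplicative library-size jitter applied
#'   to the default depths (ignored when `library_sizes` is supplied).
#' @param seed integer seed; the truth is a deterministic function of it.
#'
#' @return An object of class `"titration_truth"`: normalized molecule
#'   proportions `base_expr_A`/`base_expr_B`, `feature_lengths`,
#'   `proportions`, `n_replicates`, `library_sizes`, `noise`,
#'   `bimodal_fraction` and `seed`.
#' @examples
#' truth <- titration_truth(n_features = 200, seed = 1)
#' counts <- render_counts(truth)
#' @export
titration_truth <- function(n_features = 2000L,
                            design = titration_design(),
                            library_sizes = NULL,
                            base_depth = 8e6,
                            noise = 0.01,
                            bimodal_fraction = 0.5,
                            low_meanlog = 0, high_meanlog = 4, sdlog = 1,
                            length_meanlog = log(1500), length_sdlog = 0.6,
                            depth_jitter_sd = 0.05,
                            seed = 1L) {
  if (!is.numeric(n_features) || n_features < 2) {
    stop("value error: n_features must be >= 2", call. = FALSE)
  }
  n_features <- as.integer(n_features)
  stopifnot(inherits(design, "mixture_design"))
  if (!identical(design$pure, c("A", "B"))) {
    stop("design error: the generator models two pure types named 'A' and 'B'",
         call. = FALSE)
  }
  if (bimodal_fraction < 0 || bimodal_fraction > 1) {
    stop("value error: bimodal_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise < 0) stop("value error: noise (dispersion) must be >= 0", call. = FALSE)

  types <- names(design$replicates)
  sample_ids <- unlist(lapply(types, function(ty) {
    paste(ty, seq_len(design$replicates[[ty]]), sep = "_")
  }))

  out <- with_seed(as.integer(seed), {
    draw_expr <- function() {
      lo <- runif(n_features) < bimodal_fraction
      mu <- ifelse(lo, low_meanlog, high_meanlog)
      exp(rnorm(n_features, mean = mu, sd = sdlog))
    }
    expr_a <- draw_expr()
    expr_b <- draw_expr()
    lengths <- pmax(200, round(rlnorm(n_features, length_meanlog, length_sdlog)))
    libs <- library_sizes
    if (is.null(libs)) {
      libs <- setNames(rep(base_depth, length(sample_ids)), sample_ids)
      doubled <- intersect(c("A_1", "A_3", "A_4"), sample_ids)
      libs[doubled] <- libs[doubled] * 2
      if (depth_jitter_sd > 0) {
        libs <- libs * exp(rnorm(length(libs), 0, depth_jitter_sd))
      }
    }
    list(expr_a = expr_a, expr_b = expr_b, lengths = lengths, libs = libs)
  })

  libs <- out$libs
  if (is.null(names(libs)) || !all(sample_ids %in% names(libs))) {
    stop("value error: library_sizes must be named by sample id", call. = FALSE)
  }
  libs <- libs[sample_ids]
  if (any(libs <= 0)) stop("value error: library sizes must be positive", call. = FALSE)

  ids <- sprintf("feat_%0*d", nchar(n_features), seq_len(n_features))
  p_a <- setNames(out$expr_a / sum(out$expr_a), ids)
  p_b <- setNames(out$expr_b / sum(out$expr_b), ids)
  lengths <- setNames(as.numeric(out$lengths), ids)
  p_b <- match_mean_fragment_length(p_b, p_a, lengths)

  structure(
    list(n_features = n_features,
         base_expr_A = p_a, base_expr_B = p_b,
         feature_lengths = lengths,
         proportions = design$mixtures,
         n_replicates = design$replicates,
         library_sizes = libs,
         noise = noise,
         bimodal_fraction = bimodal_fraction,
         seed = as.integer(seed),
         design = design),
    class = "titration_truth"
  )
}

## Tilt proportions q so that sum(q) = 1 and sum(q * L) = sum(p_ref * L),
## i.e. both pure sources share one mean fragment length.  Exponential tilt
## q_i <- q_i * exp(t * L_i) / Z keeps all proportions positive; the mean
## length of the tilted distribution is strictly increasing in t, so t is
## found by root bisection.  At realistic scales t is tiny and the tilt
## perturbs each proportion by well under a percent.
match_mean_fragment_length <- function(q, p_ref, lengths) {
  s_ref <- sum(p_ref * lengths)
  if (stats::sd(lengths) == 0) return(q)  # constant lengths: already matched
  l0 <- mean(lengths)
  mean_len <- function(t) {
    w <- q * exp(t * (lengths - l0))   # centred for numerical stability
    sum(w * lengths) / sum(w)
  }
  f <- function(t) mean_len(t) - s_ref
  span <- 1 / stats::sd(lengths)
  lo <- -span; hi <- span
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  t <- stats::uniroot(f, c(lo, hi), tol = 1e-15)$root
  w <- q * exp(t * (lengths - l0))
  w <- w / sum(w)
  # affine polish: with the residual mismatch now ~0, the exact linear
  # correction w_i * (u + v*L_i) stays positive and pins the normalizer to
  # machine precision
  s_w <- sum(w * lengths)
  var_l <- sum(w * lengths^2) - s_w^2
  if (var_l > 0) {
    v <- (s_ref - s_w) / var_l
    u <- 1 - v * s_w
    polished <- w * (u + v * lengths)
    if (all(polished > 0)) w <- polished / sum(polished)
  }
  w
}

#' @export
print.titration_truth <- function(x, ...) {
  cat(sprintf("titration_truth: %d features, seed %d, dispersion %g\n",
              x$n_features, x$seed, x$noise))
  for (m in names(x$proportions)) {
    w <- x$proportions[[m]]
    cat("  ", m, " = ", paste(sprintf("%.4g*%s", w, names(w)), collapse = " + "),
        "\n", sep = "")
  }
  cat(sprintf("  library sizes: %s - %s\n",
              format(min(x$library_sizes), digits = 3),
              format(max(x$library_sizes), digits = 3)))
  invisible(x)
}

## molecule-proportion vector of any declared sample type
molecule_proportions <- function(truth, sample_type) {
  if (sample_type == "A") return(truth$base_expr_A)
  if (sample_type == "B") return(truth$base_expr_B)
  truth_mixture_vector(truth, sample_type)
}

#' Ground-truth molecule proportions of a mixture type
#'
#' The convex combination of the pure samples' normalized molecule-proportion
#' vectors with the declared weights; the generator-side reference profile
#' used in constructed-value concordance checks.
#'
#' @param truth a [titration_truth()].
#' @param mixture_type a mixture type declared in `truth$proportions`.
#' @return Named per-feature numeric vector summing to 1.
#' @export
truth_mixture_vector <- function(truth, mixture_type) {
  stopifnot(inherits(truth, "titration_truth"))
  if (!mixture_type %in% names(truth$proportions)) {
    stop(sprintf("design error: unknown mixture type '%s'", mixture_type),
         call. = FALSE)
  }
  w <- truth$proportions[[mixture_type]]
  w[["A"]] * truth$base_expr_A + w[["B"]] * truth$base_expr_B
}

#' Render a synthetic experiment as a fragment-count matrix
#'
#' For each sample, the expected count of feature i is
#' `library_size * p_i * L_i / sum_j(p_j * L_j)` with `p` the sample's
#' molecule-proportion vector and `L` the feature lengths.  With `noise = 0`
#' the matrix holds exactly these (real-valued) expectations; with
#' `noise > 0` counts are drawn gamma-Poisson (negative binomial with
#' dispersion `noise`, i.e. `size = 1/noise`), seeded from the truth so the
#' rendering is reproducible.
#'
#' @param truth a [titration_truth()].
#' @param noise dispersion override; defaults to `truth$noise`.
#' @param round_counts round to integers (format realism); noiseless
#'   expectations are left real-valued by default so exact-recovery checks
#'   can use tight tolerances.
#' @return A [quant_matrix()] with unit `"count"`.
#' @export
render_counts <- function(truth, noise = truth$noise, round_counts = FALSE) {
  stopifnot(inherits(truth, "titration_truth"))
  if (noise < 0) stop("value error: noise (dispersion) must be >= 0", call. = FALSE)
  lengths <- truth$feature_lengths
  sample_ids <- names(truth$library_sizes)
  meta <- data.frame(
    sample_id = sample_ids,
    sample_type = sub("_[0-9]+$", "", sample_ids),
    replicate = as.integer(sub("^.*_", "", sample_ids)),
    library_size = as.numeric(truth$library_sizes),
    stringsAsFactors = FALSE
  )
  expected <- vapply(seq_along(sample_ids), function(j) {
    p <- molecule_proportions(truth, meta$sample_type[j])
    frag <- p * lengths
    meta$library_size[j] * frag / sum(frag)
  }, numeric(truth$n_features))
  dimnames(expected) <- list(names(lengths), sample_ids)
  values <- expected
  if (noise > 0) {
    values <- with_seed(truth$seed + 1L, {
      v <- matrix(
        rnbinom(length(expected), mu = as.vector(expected), size = 1 / noise),
        nrow = nrow(expected), dimnames = dimnames(expected)
      )
      storage.mode(v) <- "double"
      v
    })
  }
  if (round_counts) values <- round(values)
  quant_matrix(values, meta, unit = "count", level = "gene",
               provenance = list(source = "synthetic", seed = truth$seed,
                                 dispersion = noise,
                                 lengths = lengths))
}

#' Simulate a titration experiment in one call
#'
#' Convenience wrapper: [titration_truth()] followed by [render_counts()].
#'
#' @inheritParams titration_truth
#' @param ... further arguments passed to [titration_truth()].
#' @return A list with elements `truth` and `counts`.
#' @export
simulate_titration <- function(n_features = 2000L, seed = 1L, ...) {
  truth <- titration_truth(n_features = n_features, seed = seed, ...)
  list(truth = truth, counts = render_counts(truth))
}

#' Write a simulated experiment to disk
#'
#' Emits the standard artifact set: the count matrix as a generic TSV, feature
#' lengths as a two-column TSV, the ground truth (proportions, library sizes,
#' dispersion, seed) as JSON, and the design as YAML.
#'
#' @param sim a list as returned by [simulate_titration()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim$truth, "titration_truth"),
            inherits(sim$counts, "quant_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "feature_lengths.tsv"),
    truth = file.path(dir, "truth.json"),
    design = file.path(dir, "design.yaml")
  )
  write_quant_matrix(sim$counts, paths$counts)
  lens <- data.frame(feature_id = names(sim$truth$feature_lengths),
                     length = as.numeric(sim$truth$feature_lengths))
  write.table(lens, paths$lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(n_features = truth$n_features,
         proportions = lapply(truth$proportions, as.list),
         n_replicates = as.list(truth$n_replicates),
         library_sizes = as.list(truth$library_sizes),
         noise = truth$noise,
         bimodal_fraction = truth$bimodal_fraction,
         seed = truth$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_design(truth$design, paths$design)
  invisible(paths)
}
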