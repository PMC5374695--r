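## End-to-end orchestration: load or simulate -> convert units -> fit ->
## assess -> write artifacts.  One directory per (mixture, unit) with fixed
## filenames, plus a per-mixture summary, so downstream reporting is
## path-predictable.  Identical config + inputs produce byte-identical
## artifacts.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with either a `simulate`
#' block (arguments for [titration_truth()]) or a `matrix` path (generic TSV)
#' plus optional `lengths` path; a `design` path or [mixture_design()]
#' (defaulting to the canonical titration design); `units` to evaluate
#' (subset of count/TPM/FPKM/log), `mixtures` to evaluate, `out` directory,
#' `n_grid` for the ROC-like threshold grid, and `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return The validated, completed configuration (invisibly usable by
#'   [run_pipeline()]).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("validation error: config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("validation error: config must be a list", call. = FALSE)
  defaults <- list(units = c("count", "TPM", "FPKM", "log"),
                   mixtures = "C", n_grid = 101L, seed = 1L, out = NULL)
  config <- modifyList(defaults, config)
  if (is.null(config$simulate) && is.null(config$matrix)) {
    stop("validation error: config needs either a 'simulate' block or a 'matrix' path",
         call. = FALSE)
  }
  if (!is.null(config$matrix) && !file.exists(config$matrix)) {
    stop("validation error: matrix file not found: ", config$matrix, call. = FALSE)
  }
  if (!is.null(config$lengths) && is.character(config$lengths) &&
      !file.exists(config$lengths)) {
    stop("validation error: lengths file not found: ", config$lengths, call. = FALSE)
  }
  if (is.character(config$design) && !file.exists(config$design)) {
    stop("validation error: design file not found: ", config$design, call. = FALSE)
  }
  bad <- setdiff(config$units, c("count", "TPM", "FPKM", "log"))
  if (length(bad)) {
    stop("validation error: unsupported unit(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  config
}

#' Run the full linearity-evaluation pipeline
#'
#' Loads (or simulates) a count matrix, derives the requested quantification
#' units, and for every requested mixture type evaluates every unit
#' ([evaluate_unit()]) on a shared ROC threshold grid, ranks the units
#' ([summarize_methods()]), and writes JSON and TSV artifacts under
#' `config$out` (when set): per unit `aggregate_fit.json`,
#' `coefficients.tsv`, `roc.tsv`, `rank_constructed.tsv`, `rank_fitted.tsv`,
#' `rescaled_residuals.tsv`; per mixture `summary.tsv`/`summary.json`; plus
#' the resolved `config.yaml` and a `run.log` recording package version,
#' seed and config hash.
#'
#' @param config named list or YAML path; see [validate_config()].
#' @return Invisibly, a list with `summaries` (one ranked data frame per
#'   mixture type), `evaluations`, and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  config <- stage("validate", validate_config(config))

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    truth <- stage("simulate", do.call(titration_truth, sim_args))
    counts <- stage("simulate", render_counts(truth))
    design <- truth$design
    lengths <- truth$feature_lengths
  } else {
    counts <- stage("load", read_quant_matrix(config$matrix, format = "generic_tsv",
                                              unit = "count"))
    lengths <- if (!is.null(config$lengths)) {
      stage("load", read_feature_lengths(config$lengths))
    } else NULL
    design <- if (is.null(config$design)) titration_design()
      else if (inherits(config$design, "mixture_design")) config$design
      else stage("load", read_design(config$design))
  }

  matrices <- stage("convert", {
    out <- list()
    for (u in config$units) out[[u]] <- convert_unit(counts, u, lengths)
    out
  })

  out_dir <- config$out
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summaries <- list()
  evaluations <- list()
  for (mix in config$mixtures) {
    # shared ROC grid: pooled combination-averaged |residuals| over all units
    fits <- stage(paste0("fit/", mix), lapply(matrices, mixlin,
                                              design = design, mixture = mix))
    grid <- pooled_thresholds(lapply(fits, residuals), n_grid = config$n_grid)
    evs <- stage(paste0("evaluate/", mix), lapply(names(matrices), function(u) {
      evaluate_unit(matrices[[u]], design, mixture = mix,
                    thresholds = grid, label = u)
    }))
    names(evs) <- names(matrices)
    summaries[[mix]] <- summarize_methods(evs)
    evaluations[[mix]] <- evs
    if (!is.null(out_dir)) {
      stage(paste0("write/", mix),
            write_mixture_artifacts(out_dir, mix, evs, summaries[[mix]]))
    }
  }

  if (!is.null(out_dir)) {
    stage("write", {
      cfg_path <- file.path(out_dir, "config.yaml")
      writable <- config
      writable$out <- NULL   # location is self-evident; keep artifacts path-free
      if (inherits(writable$design, "mixture_design")) writable$design <- "<in-memory>"
      yaml::write_yaml(writable, cfg_path)
      hash <- unname(tools::md5sum(cfg_path))
      writeLines(c(
        sprintf("mixlin %s", as.character(utils::packageVersion("mixlin"))),
        sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
        sprintf("seed %d", as.integer(config$seed)),
        sprintf("config_md5 %s", hash),
        sprintf("mixtures %s", paste(config$mixtures, collapse = ",")),
        sprintf("units %s", paste(config$units, collapse = ","))
      ), file.path(out_dir, "run.log"))
    })
  }

  invisible(list(summaries = summaries, evaluations = evaluations,
                 truth = truth, config = config))
}

write_tsv <- function(df, path, digits_fmt = "%.10g") {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf(digits_fmt, x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_mixture_artifacts <- function(out_dir, mixture, evaluations, summary_tab) {
  mix_dir <- file.path(out_dir, mixture)
  dir.create(mix_dir, recursive = TRUE, showWarnings = FALSE)
  for (ev in evaluations) {
    u_dir <- file.path(mix_dir, ev$label)
    dir.create(u_dir, showWarnings = FALSE)
    fit <- ev$fit
    jsonlite::write_json(
      list(unit = ev$label, mixture = mixture,
           n_combinations = fit$n_combinations,
           n_features = fit$n_features, n_dropped = fit$n_dropped,
           coefficients = as.list(fit$coefficients),
           expected = as.list(fit$expected),
           ci_percentile = list(lower = as.list(fit$ci_percentile["2.5%", ]),
                                upper = as.list(fit$ci_percentile["97.5%", ])),
           mean_r_squared = mean(fit$r_squared),
           spearman_constructed = ev$concordance_constructed$spearman,
           spearman_fitted = ev$concordance_fitted$spearman,
           auc_like = ev$roc$auc_like,
           rescaled_rms = sqrt(mean(ev$rescaled$residuals^2))),
      file.path(u_dir, "aggregate_fit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_tsv(cbind(fit$combinations, as.data.frame(fit$coef_samples),
                    r_squared = fit$r_squared),
              file.path(u_dir, "coefficients.tsv"))
    write_tsv(data.frame(threshold = ev$roc$thresholds,
                         proportion = ev$roc$proportions),
              file.path(u_dir, "roc.tsv"))
    write_tsv(ev$concordance_constructed$rank_pairs,
              file.path(u_dir, "rank_constructed.tsv"))
    write_tsv(ev$concordance_fitted$rank_pairs,
              file.path(u_dir, "rank_fitted.tsv"))
    write_tsv(data.frame(fitted = ev$rescaled$fitted,
                         residual = ev$rescaled$residuals),
              file.path(u_dir, "rescaled_residuals.tsv"))
  }
  write_tsv(summary_tab, file.path(mix_dir, "summary.tsv"))
  jsonlite::write_json(summary_tab, file.path(mix_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(mix_dir)
}
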