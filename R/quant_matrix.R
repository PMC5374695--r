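#' Construct a feature-by-sample abundance matrix
#'
#' The container used throughout the package: a numeric matrix of abundances
#' (features in rows, samples in columns) together with per-sample metadata
#' and a unit tag.  Values must be non-negative for the linear-scale units
#' (`count`, `TPM`, `FPKM`); the `log` unit may hold any real values.
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   colnames (sample ids).
#' @param sample_meta data frame with columns `sample_id`, `sample_type`,
#'   `replicate` and `library_size`, one row per column of `values` in the
#'   same order.
#' @param unit one of `"count"`, `"TPM"`, `"FPKM"`, `"log"`.
#' @param level `"gene"` or `"isoform"`; the pipeline is agnostic to which.
#' @param provenance free-form list recording origin (source format, the unit
#'   a `log` matrix was derived from, per-feature lengths if the source
#'   provided them).
#'
#' @return An object of class `"quant_matrix"`.
#' @export
quant_matrix <- function(values, sample_meta, unit = c("count", "TPM", "FPKM", "log"),
                         level = c("gene", "isoform"), provenance = list()) {
  unit <- match.arg(unit)
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("data error: feature ids must be present and unique", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("data error: sample ids must be present and unique", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("data error: abundance values must be finite", call. = FALSE)
  }
  if (unit != "log" && any(values < 0)) {
    stop(sprintf("value error: negative values are not allowed for unit '%s'", unit),
         call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample_id", "sample_type", "replicate", "library_size")
  if (!all(req %in% names(sample_meta))) {
    stop("data error: sample_meta needs columns ",
         paste(setdiff(req, names(sample_meta)), collapse = ", "), call. = FALSE)
  }
  if (nrow(sample_meta) != ncol(values) ||
      !identical(as.character(sample_meta$sample_id), colnames(values))) {
    stop("data error: sample_meta rows must match matrix columns in order",
         call. = FALSE)
  }
  rownames(sample_meta) <- NULL
  structure(
    list(values = values, sample_meta = sample_meta, unit = unit,
         level = level, provenance = provenance),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d features x %d samples, unit %s, level %s\n",
              nrow(x$values), ncol(x$values), x$unit, x$level))
  tab <- table(x$sample_meta$sample_type)
  cat("  samples: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  cat("  library sizes: ",
      paste(format(range(x$sample_meta$library_size), digits = 3), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Columns of a quant_matrix belonging to one sample type
#'
#' @param m a [quant_matrix()].
#' @param sample_type a sample type present in `m$sample_meta`.
#' @return Numeric matrix of the matching columns, ordered by replicate index.
#' @export
sample_columns <- function(m, sample_type) {
  stopifnot(inherits(m, "quant_matrix"))
  idx <- which(m$sample_meta$sample_type == sample_type)
  if (length(idx) == 0L) {
    stop(sprintf("data error: no samples of type '%s' in matrix", sample_type),
         call. = FALSE)
  }
  idx <- idx[order(m$sample_meta$replicate[idx])]
  m$values[, idx, drop = FALSE]
}

## type-mean column over replicates, used by concordance analyses
type_mean <- function(m, sample_type) {
  rowMeans(sample_columns(m, sample_type))
}

## check that a matrix carries every replicate a design declares
check_matrix_design <- function(m, design) {
  for (ty in names(design$replicates)) {
    n <- sum(m$sample_meta$sample_type == ty)
    if (n < design$replicates[[ty]]) {
      stop(sprintf(
        "data error: design declares %d replicates of '%s' but matrix has %d",
        design$replicates[[ty]], ty, n), call. = FALSE)
    }
  }
  invisible(TRUE)
}
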