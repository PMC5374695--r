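## Quantification-unit conversions.  Standard definitions:
##   TPM_i  = 1e6 * (count_i / length_i) / sum_j (count_j / length_j)
##   FPKM_i = count_i * 1e9 / (length_i * sum_j count_j)
## RPKM (single-end) is treated as synonymous with FPKM.

resolve_lengths <- function(m, lengths) {
  if (is.null(lengths)) lengths <- m$provenance$lengths
  if (is.null(lengths)) {
    stop("value error: feature lengths required and none attached to the matrix",
         call. = FALSE)
  }
  lengths <- unlist(lengths)
  if (is.null(names(lengths))) {
    stop("value error: feature lengths must be named by feature id", call. = FALSE)
  }
  missing <- setdiff(rownames(m$values), names(lengths))
  if (length(missing)) {
    stop("data error: lengths missing for features: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  lengths <- lengths[rownames(m$values)]
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("value error: feature lengths must be positive and finite", call. = FALSE)
  }
  lengths
}

check_no_zero_samples <- function(m) {
  zero <- colSums(m$values) == 0
  if (any(zero)) {
    stop("value error: normalization undefined for all-zero sample(s): ",
         paste(colnames(m$values)[zero], collapse = ", "), call. = FALSE)
  }
}

#' Convert a count matrix to TPM
#'
#' Per sample, counts are divided by feature length to give a per-feature
#' sampling rate, and rates are rescaled to sum to one million, so every TPM
#' column sums to 1e6 and is invariant to sequencing depth.
#'
#' @param m a [quant_matrix()] with unit `"count"`.
#' @param lengths named per-feature lengths (bases); taken from the matrix
#'   provenance when omitted and available.
#' @return A [quant_matrix()] with unit `"TPM"`.
#' @examples
#' sim <- simulate_titration(n_features = 50, seed = 1)
#' tpm <- counts_to_tpm(sim$counts)
#' colSums(tpm$values)[1:2]   # 1e6 each
#' @export
counts_to_tpm <- function(m, lengths = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$unit != "count") {
    stop(sprintf("value error: expected unit 'count', got '%s'", m$unit), call. = FALSE)
  }
  lengths <- resolve_lengths(m, lengths)
  check_no_zero_samples(m)
  rate <- m$values / lengths
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  quant_matrix(tpm, m$sample_meta, unit = "TPM", level = m$level,
               provenance = c(m$provenance[setdiff(names(m$provenance), "lengths")],
                              list(derived_from = "count", lengths = lengths)))
}

#' Convert a count matrix to FPKM
#'
#' `FPKM_i = count_i * 1e9 / (length_i * total_counts)` per sample: fragments
#' per kilobase of feature per million mapped fragments.
#'
#' @inheritParams counts_to_tpm
#' @return A [quant_matrix()] with unit `"FPKM"`.
#' @export
counts_to_fpkm <- function(m, lengths = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$unit != "count") {
    stop(sprintf("value error: expected unit 'count', got '%s'", m$unit), call. = FALSE)
  }
  lengths <- resolve_lengths(m, lengths)
  check_no_zero_samples(m)
  fpkm <- sweep(m$values / lengths, 2L, colSums(m$values), "/") * 1e9
  quant_matrix(fpkm, m$sample_meta, unit = "FPKM", level = m$level,
               provenance = c(m$provenance[setdiff(names(m$provenance), "lengths")],
                              list(derived_from = "count", lengths = lengths)))
}

#' Log-transform an abundance matrix
#'
#' `log2(x + 1)`: the pseudocount keeps zeros at zero and the base-2 scale is
#' the field's convention.  The original unit is recorded in provenance.
#'
#' @param m a [quant_matrix()] with non-negative values.
#' @return A [quant_matrix()] with unit `"log"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (any(m$values < 0)) {
    stop("value error: log transform requires non-negative values", call. = FALSE)
  }
  quant_matrix(log2(m$values + 1), m$sample_meta, unit = "log", level = m$level,
               provenance = c(m$provenance, list(log_of = m$unit)))
}

#' Convert a count matrix to a requested unit
#'
#' Dispatch helper used by the pipeline: `"count"` returns the input,
#' `"TPM"`/`"FPKM"` convert with [counts_to_tpm()]/[counts_to_fpkm()], and
#' `"log"` applies [log_transform()] to the counts.
#'
#' @inheritParams counts_to_tpm
#' @param unit target unit.
#' @return A [quant_matrix()] in the requested unit.
#' @export
convert_unit <- function(m, unit = c("count", "TPM", "FPKM", "log"), lengths = NULL) {
  unit <- match.arg(unit)
  switch(unit,
         count = m,
         TPM = counts_to_tpm(m, lengths),
         FPKM = counts_to_fpkm(m, lengths),
         log = log_transform(m))
}
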