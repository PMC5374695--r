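## Readers and writers for abundance tables.
##
## The generic interchange format is a TSV with `feature_id` in the first
## column and one column per sample (header row = sample ids).  Adapters parse
## the native per-sample output tables of HTSeq, Kallisto, Salmon, RSEM and
## Cufflinks; per-sample formats take one file per sample.

adapter_spec <- list(
  kallisto = list(id = "target_id", header = TRUE,
                  cols = c(count = "est_counts", tpm = "tpm"),
                  length_col = "eff_length"),
  salmon = list(id = "Name", header = TRUE,
                cols = c(count = "NumReads", tpm = "TPM"),
                length_col = "EffectiveLength"),
  rsem = list(id = NA, header = TRUE,   # first column: gene_id or transcript_id
              cols = c(count = "expected_count", tpm = "TPM", fpkm = "FPKM"),
              length_col = "effective_length"),
  cufflinks = list(id = "tracking_id", header = TRUE,
                   cols = c(fpkm = "FPKM"), length_col = NULL)
)

unit_for_value <- function(value) {
  switch(value, count = "count", tpm = "TPM", fpkm = "FPKM")
}

read_one_sample <- function(path, format, value) {
  if (!file.exists(path)) {
    stop(sprintf("value error: file not found: %s", path), call. = FALSE)
  }
  if (format == "htseq") {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) {
      stop(sprintf("format error: htseq file %s needs two columns", path),
           call. = FALSE)
    }
    keep <- !startsWith(as.character(tab[[1L]]), "__")
    return(list(ids = as.character(tab[[1L]][keep]),
                values = as.numeric(tab[[2L]][keep]), lengths = NULL))
  }
  spec <- adapter_spec[[format]]
  tab <- read.delim(path, header = spec$header, stringsAsFactors = FALSE,
                    check.names = FALSE)
  col <- spec$cols[value]
  if (is.na(col)) {
    stop(sprintf("format error: %s tables do not carry a '%s' column", format, value),
         call. = FALSE)
  }
  if (!col %in% names(tab)) {
    stop(sprintf("format error: missing column '%s' in %s file %s", col, format, path),
         call. = FALSE)
  }
  id_col <- if (is.na(spec$id)) names(tab)[1L] else spec$id
  if (!id_col %in% names(tab)) {
    stop(sprintf("format error: missing column '%s' in %s file %s", id_col, format, path),
         call. = FALSE)
  }
  lens <- NULL
  if (!is.null(spec$length_col)) {
    lcol <- intersect(c(spec$length_col, "length", "Length"), names(tab))[1]
    if (!is.na(lcol)) lens <- setNames(as.numeric(tab[[lcol]]), tab[[id_col]])
  }
  list(ids = as.character(tab[[id_col]]), values = as.numeric(tab[[col]]),
       lengths = lens)
}

#' Read an abundance matrix
#'
#' `format = "generic_tsv"` reads one feature-by-sample table.  The per-sample
#' formats (`htseq`, `kallisto`, `salmon`, `rsem`, `cufflinks`) read one file
#' per sample and assemble the matrix; supply a named vector of paths (names
#' become sample ids).  Units are inferred per format: HTSeq yields counts;
#' Kallisto/Salmon yield counts or TPM depending on `value`; RSEM yields
#' counts, TPM or FPKM; Cufflinks yields FPKM.  HTSeq trailing summary rows
#' (`__no_feature` etc.) are dropped.  RPKM tables can be read through the
#' FPKM path.
#'
#' @param path file path (`generic_tsv`) or named character vector of
#'   per-sample file paths.
#' @param format table dialect.
#' @param value which column to extract from multi-column per-sample formats:
#'   `"count"`, `"tpm"` or `"fpkm"`.
#' @param unit unit tag of a generic TSV (the generic format does not encode
#'   it).
#' @param sample_meta optional data frame with columns `sample_id`,
#'   `sample_type`, `replicate` and optionally `library_size`; when omitted,
#'   sample ids of the form `"<type>_<replicate>"` are parsed and library
#'   sizes default to column totals.
#' @param level `"gene"` or `"isoform"`.
#' @return A [quant_matrix()]; per-sample formats that report feature lengths
#'   attach them to the provenance so unit conversions can reuse them.
#' @export
read_quant_matrix <- function(path,
                              format = c("generic_tsv", "htseq", "kallisto",
                                         "salmon", "rsem", "cufflinks"),
                              value = c("count", "tpm", "fpkm"),
                              unit = "count",
                              sample_meta = NULL,
                              level = c("gene", "isoform")) {
  format <- match.arg(format)
  value <- match.arg(value)
  level <- match.arg(level)

  if (format == "generic_tsv") {
    if (length(path) != 1L || !file.exists(path)) {
      stop(sprintf("value error: file not found: %s", path[1]), call. = FALSE)
    }
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (names(tab)[1L] != "feature_id") {
      stop("format error: missing column 'feature_id' (must be first) in generic TSV",
           call. = FALSE)
    }
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids)) {
      stop("data error: duplicate feature ids in ", path, call. = FALSE)
    }
    values <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(values) <- ids
    meta <- build_sample_meta(colnames(values), sample_meta, values)
    return(quant_matrix(values, meta, unit = unit, level = level,
                        provenance = list(source = format, path = path)))
  }

  paths <- path
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("value error: per-sample formats need a named vector of paths ",
         "(names = sample ids)", call. = FALSE)
  }
  parsed <- lapply(paths, read_one_sample, format = format, value = value)
  ref_ids <- parsed[[1L]]$ids
  if (anyDuplicated(ref_ids)) {
    stop("data error: duplicate feature ids in ", paths[[1L]], call. = FALSE)
  }
  for (j in seq_along(parsed)[-1L]) {
    ids_j <- parsed[[j]]$ids
    if (!identical(sort(ids_j), sort(ref_ids))) {
      only_ref <- setdiff(ref_ids, ids_j)
      only_j <- setdiff(ids_j, ref_ids)
      stop(sprintf(
        "data error: feature sets differ between %s and %s (only in first: %s; only in %s: %s)",
        names(paths)[1L], names(paths)[j],
        paste(head(only_ref, 3), collapse = ","),
        names(paths)[j], paste(head(only_j, 3), collapse = ",")), call. = FALSE)
    }
  }
  values <- vapply(parsed, function(p) p$values[match(ref_ids, p$ids)],
                   numeric(length(ref_ids)))
  dimnames(values) <- list(ref_ids, names(paths))
  meta <- build_sample_meta(colnames(values), sample_meta, values)
  lens <- parsed[[1L]]$lengths
  if (!is.null(lens)) lens <- lens[ref_ids]
  quant_matrix(values, meta,
               unit = if (format == "htseq") "count" else unit_for_value(value),
               level = level,
               provenance = list(source = format, paths = unname(paths),
                                 lengths = lens))
}

build_sample_meta <- function(sample_ids, sample_meta, values) {
  if (is.null(sample_meta)) {
    typed <- grepl("^.+_[0-9]+$", sample_ids)
    sample_meta <- data.frame(
      sample_id = sample_ids,
      sample_type = ifelse(typed, sub("_[0-9]+$", "", sample_ids), sample_ids),
      replicate = ifelse(typed, as.integer(sub("^.*_", "", sample_ids)), 1L),
      library_size = colSums(values),
      stringsAsFactors = FALSE
    )
    return(sample_meta)
  }
  sample_meta <- as.data.frame(sample_meta)
  if (!all(c("sample_id", "sample_type", "replicate") %in% names(sample_meta))) {
    stop("data error: sample_meta needs sample_id, sample_type, replicate",
         call. = FALSE)
  }
  if (!setequal(sample_meta$sample_id, sample_ids)) {
    stop("data error: sample_meta ids do not match matrix samples", call. = FALSE)
  }
  sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), , drop = FALSE]
  if (is.null(sample_meta$library_size)) sample_meta$library_size <- colSums(values)
  sample_meta
}

#' Write an abundance matrix as a generic TSV
#'
#' First column `feature_id`, one column per sample, header row of sample
#' ids, values printed with `%.10g` so a read/write round trip is lossless at
#' working precision.
#'
#' @param m a [quant_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_quant_matrix <- function(m, path) {
  stopifnot(inherits(m, "quant_matrix"))
  tab <- cbind(
    feature_id = rownames(m$values),
    as.data.frame(matrix(sprintf("%.10g", m$values), nrow = nrow(m$values),
                         dimnames = dimnames(m$values)),
                  check.names = FALSE)
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-feature lengths from a two-column TSV
#'
#' @param path TSV with columns `feature_id` and `length`.
#' @return Named numeric vector of lengths.
#' @export
read_feature_lengths <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "length") %in% names(tab))) {
    stop("format error: missing column 'feature_id' or 'length' in ", path,
         call. = FALSE)
  }
  setNames(as.numeric(tab$length), as.character(tab$feature_id))
}

#' Read or write a mixture design as YAML
#'
#' The on-disk design file holds `pure`, `mixtures` (named weight maps) and
#' `replicates`.
#'
#' @param path YAML file path.
#' @return `read_design()` returns a [mixture_design()]; `write_design()`
#'   invisibly returns `path`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("value error: design file not found: %s", path), call. = FALSE)
  }
  spec <- yaml::read_yaml(path)
  mixture_design(
    pure = as.character(unlist(spec$pure)),
    mixtures = lapply(spec$mixtures, unlist),
    replicates = unlist(spec$replicates)
  )
}

#' @rdname read_design
#' @param design a [mixture_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mixture_design"))
  yaml::write_yaml(
    list(pure = as.list(design$pure),
         mixtures = lapply(design$mixtures, as.list),
         replicates = as.list(design$replicates)),
    path
  )
  invisible(path)
}
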