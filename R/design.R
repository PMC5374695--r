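#' Declare a titration mixture design
#'
#' A mixture design records which sample types are pure RNA sources, how each
#' mixture type is composed from them, and how many replicates of each sample
#' type the experiment contains.  The canonical benchmark design has pure
#' samples A and B, mixture C = 0.75*A + 0.25*B and mixture D = 0.25*A +
#' 0.75*B, with four replicates of every type.
#'
#' @param pure character vector of at least two pure sample types, in a fixed
#'   order (the order of the regression coefficients).
#' @param mixtures named list; each element is a named numeric vector of
#'   component weights over `pure`, with weights in `[0, 1]` summing to 1
#'   (tolerance 1e-12).
#' @param replicates named integer vector giving the replicate count of every
#'   sample type (pure and mixture); all counts must be >= 1.
#'
#' @return An object of class `"mixture_design"`.
#' @examples
#' titration_design()                  # the canonical A/B/C/D design
#' mixture_design(
#'   pure = c("A", "B"),
#'   mixtures = list(C = c(A = 0.75, B = 0.25)),
#'   replicates = c(A = 2, B = 2, C = 2)
#' )
#' @export
mixture_design <- function(pure, mixtures, replicates) {
  if (!is.character(pure) || length(pure) < 2L || anyDuplicated(pure)) {
    stop("design error: need at least two distinct pure sample types", call. = FALSE)
  }
  if (!is.list(mixtures) || is.null(names(mixtures)) || any(names(mixtures) == "")) {
    stop("design error: 'mixtures' must be a named list of weight vectors", call. = FALSE)
  }
  if (any(names(mixtures) %in% pure)) {
    stop("design error: mixture types must be distinct from pure types", call. = FALSE)
  }
  mixtures <- lapply(mixtures, function(w) {
    w <- unlist(w)
    if (is.null(names(w)) || !all(names(w) %in% pure)) {
      stop("design error: mixture weights must be named by declared pure types",
           call. = FALSE)
    }
    full <- setNames(numeric(length(pure)), pure)
    full[names(w)] <- as.numeric(w)
    if (any(full < 0) || any(full > 1)) {
      stop("design error: mixture weights must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(full) - 1) > 1e-12) {
      stop(sprintf("design error: mixture weights sum to %.15g, not 1", sum(full)),
           call. = FALSE)
    }
    full
  })
  replicates <- unlist(replicates)
  types <- c(pure, names(mixtures))
  if (is.null(names(replicates)) || !all(types %in% names(replicates))) {
    stop("design error: 'replicates' must name every sample type", call. = FALSE)
  }
  replicates <- replicates[types]
  if (any(replicates < 1) || any(replicates != round(replicates))) {
    stop("design error: replicate counts must be positive integers", call. = FALSE)
  }
  structure(
    list(pure = pure, mixtures = mixtures,
         replicates = setNames(as.integer(replicates), types)),
    class = "mixture_design"
  )
}

#' @rdname mixture_design
#' @param n_replicates replicate count shared by all four sample types of the
#'   canonical design.
#' @export
titration_design <- function(n_replicates = 4L) {
  mixture_design(
    pure = c("A", "B"),
    mixtures = list(C = c(A = 0.75, B = 0.25), D = c(A = 0.25, B = 0.75)),
    replicates = setNames(rep(n_replicates, 4L), c("A", "B", "C", "D"))
  )
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("Mixture design\n")
  cat("  pure types: ", paste(x$pure, collapse = ", "), "\n", sep = "")
  for (m in names(x$mixtures)) {
    w <- x$mixtures[[m]]
    cat("  ", m, " = ", paste(sprintf("%.4g*%s", w, names(w)), collapse = " + "),
        "\n", sep = "")
  }
  cat("  replicates: ",
      paste(sprintf("%s:%d", names(x$replicates), x$replicates), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate replicate combinations for a mixture model
#'
#' Every model fit uses one replicate of each pure type and one replicate of
#' the mixture type, so a design with r replicates per type yields r^(k+1)
#' models (64 in the canonical 4-replicate two-source design).  Combinations
#' are returned in lexicographic order with the first pure type varying
#' slowest and the mixture replicate varying fastest.
#'
#' @param design a [mixture_design()].
#' @param mixture_type name of the mixture type to model.
#' @return A data frame with one integer column per involved sample type
#'   (pure types in design order, then the mixture type) and one row per
#'   combination.
#' @examples
#' nrow(enumerate_combinations(titration_design(), "C"))  # 64
#' @export
enumerate_combinations <- function(design, mixture_type) {
  stopifnot(inherits(design, "mixture_design"))
  if (!mixture_type %in% names(design$mixtures)) {
    stop(sprintf("design error: unknown mixture type '%s'", mixture_type),
         call. = FALSE)
  }
  types <- c(design$pure, mixture_type)
  counts <- design$replicates[types]
  # expand.grid varies the first factor fastest; reverse to get lexicographic
  # order (first type most significant)
  grid <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(types)), drop = FALSE]
  names(grid) <- types
  rownames(grid) <- NULL
  grid
}
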