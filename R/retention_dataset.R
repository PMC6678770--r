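#' Chromatographic condition metadata
#'
#' Records the column and gradient program under which a set of retention
#' times was measured. All fields are optional; they are carried along as
#' metadata and never enter any computation.
#'
#' @param column_name Stationary phase / column identifier (character).
#' @param gradient_time Gradient time t_G in minutes (> 0), or `NA`.
#' @param temperature Column temperature T in degrees Celsius (> 0), or `NA`.
#'
#' @return An object of class `chromatographic_condition`.
#' @export
#' @examples
#' chromatographic_condition("Supelcosil LC-18", gradient_time = 10, temperature = 35)
chromatographic_condition <- function(column_name = NA_character_,
                                      gradient_time = NA_real_,
                                      temperature = NA_real_) {
  if (!is.na(gradient_time) && gradient_time <= 0) {
    stop("'gradient_time' must be > 0 minutes", call. = FALSE)
  }
  if (!is.na(temperature) && temperature <= 0) {
    stop("'temperature' must be > 0 degrees C", call. = FALSE)
  }
  structure(
    list(column_name = as.character(column_name),
         gradient_time = as.numeric(gradient_time),
         temperature = as.numeric(temperature)),
    class = "chromatographic_condition"
  )
}

#' @export
format.chromatographic_condition <- function(x, ...) {
  parts <- character(0)
  if (!is.na(x$column_name)) parts <- c(parts, x$column_name)
  if (!is.na(x$gradient_time)) parts <- c(parts, sprintf("tG = %g min", x$gradient_time))
  if (!is.na(x$temperature)) parts <- c(parts, sprintf("T = %g °C", x$temperature))
  if (length(parts) == 0) "<unspecified condition>" else paste(parts, collapse = ", ")
}

#' @export
print.chromatographic_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Retention dataset
#'
#' The central container: analyte identifiers, a numeric descriptor matrix
#' `X` (n rows, K descriptors), and experimental retention times `y` in
#' minutes. Retention times must be strictly positive because the
#' percentage-RMSE metric divides by them.
#'
#' @param ids Character vector of unique analyte identifiers (length n).
#' @param X Numeric matrix (n x K) of molecular descriptor values, K >= 1.
#'   Descriptor values are supplied by the user, never computed here; typical
#'   choices are the total dipole moment, the most negative atomic partial
#'   charge and the solvent-accessible surface area for small molecules, or
#'   log-sum amino-acid retention, log van der Waals volume and clogP for
#'   peptides.
#' @param y Numeric vector of experimental retention times t_R (minutes, > 0).
#' @param descriptor_names Optional K labels; defaults to `colnames(X)` or
#'   `x1..xK`.
#' @param condition A [chromatographic_condition()].
#'
#' @return An object of class `retention_dataset` with fields `ids`, `X`,
#'   `y`, `condition`.
#' @export
#' @examples
#' ds <- retention_dataset(
#'   ids = c("benzene", "toluene", "phenol"),
#'   X = matrix(c(0.0, 0.4, 1.6, 110, 127, 104), ncol = 2,
#'              dimnames = list(NULL, c("mu", "SASA"))),
#'   y = c(12.1, 14.8, 6.3)
#' )
#' ds
retention_dataset <- function(ids, X, y, descriptor_names = NULL,
                              condition = chromatographic_condition()) {
  ids <- as.character(ids)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(ids)
  if (n < 1) stop("dataset must contain at least one analyte", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate analyte ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (nrow(X) != n || length(y) != n) {
    stop("'ids', rows of 'X' and 'y' must all have the same length", call. = FALSE)
  }
  if (ncol(X) < 1) stop("at least one descriptor column is required", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("descriptor matrix contains missing or non-finite values", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop("retention times contain missing or non-finite values", call. = FALSE)
  }
  if (any(y <= 0)) {
    bad <- ids[y <= 0]
    stop("retention times must be > 0 (relative-error metric divides by t_R); ",
         "offending analytes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(descriptor_names)) {
    descriptor_names <- colnames(X)
    if (is.null(descriptor_names)) descriptor_names <- paste0("x", seq_len(ncol(X)))
  }
  if (length(descriptor_names) != ncol(X)) {
    stop("'descriptor_names' must have one label per descriptor column", call. = FALSE)
  }
  colnames(X) <- descriptor_names
  rownames(X) <- NULL
  if (!inherits(condition, "chromatographic_condition")) {
    stop("'condition' must be a chromatographic_condition object", call. = FALSE)
  }
  structure(list(ids = ids, X = X, y = y, condition = condition),
            class = "retention_dataset")
}

#' Number of analytes in a retention dataset
#' @param ds A [retention_dataset()].
#' @return Integer count of analytes.
#' @export
n_analytes <- function(ds) {
  stopifnot(inherits(ds, "retention_dataset"))
  length(ds$ids)
}

#' Number of descriptors in a retention dataset
#' @param ds A [retention_dataset()].
#' @return Integer count of descriptor columns.
#' @export
n_descriptors <- function(ds) {
  stopifnot(inherits(ds, "retention_dataset"))
  ncol(ds$X)
}

#' @export
print.retention_dataset <- function(x, ...) {
  cat(sprintf("Retention dataset: %d analytes, %d descriptors (%s)\n",
              n_analytes(x), n_descriptors(x),
              paste(colnames(x$X), collapse = ", ")))
  cat("Condition:", format(x$condition), "\n")
  cat(sprintf("t_R range: %.3f - %.3f min\n", min(x$y), max(x$y)))
  invisible(x)
}

#' Subset a retention dataset by row indices
#' @param ds A [retention_dataset()].
#' @param idx Integer vector of row indices.
#' @return A [retention_dataset()] with the selected analytes, in `idx` order.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "retention_dataset"))
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > n_analytes(ds))) {
    stop("subset indices out of range", call. = FALSE)
  }
  retention_dataset(ds$ids[idx], ds$X[idx, , drop = FALSE], ds$y[idx],
                    condition = ds$condition)
}

#' Sort a dataset by ascending retention time
#'
#' Rows are permuted so that `y` is non-decreasing. Ties keep their input
#' order (stable sort), so results are deterministic even with duplicated
#' retention times. The order-constrained fit builds its adjacent-pair
#' constraints on a dataset sorted this way.
#'
#' @param ds A [retention_dataset()].
#' @return A [retention_dataset()] sorted by `y`.
#' @export
#' @examples
#' ds <- retention_dataset(c("a", "b", "c"),
#'                         matrix(1:3, ncol = 1), c(3.2, 1.1, 2.0))
#' sort_by_retention(ds)$ids  # "b" "c" "a"
sort_by_retention <- function(ds) {
  stopifnot(inherits(ds, "retention_dataset"))
  ord <- order(ds$y)   # radix order is stable
  subset_dataset(ds, ord)
}

#' Elution ranks of a vector of retention times
#'
#' Rank 1 is the earliest-eluting analyte. Ranks are 1-based so that the
#' order-%RMSE denominator is never zero. Ties are broken by input position
#' (stable), making downstream order metrics deterministic.
#'
#' @param times Numeric vector of (predicted or experimental) retention times.
#' @return Integer vector: a permutation of `1:length(times)`.
#' @export
#' @examples
#' elution_ranks(c(3.2, 1.1, 2.0))  # 3 1 2
#' elution_ranks(c(2.0, 2.0, 1.0))  # 2 3 1
elution_ranks <- function(times) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("retention times must be finite to rank", call. = FALSE)
  }
  rank(times, ties.method = "first")
}
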