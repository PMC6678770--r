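#' Kennard-Stone training/validation split
#'
#' Deterministic max-min subset selection in descriptor space. Descriptor
#' columns are autoscaled (zero mean, unit variance) before Euclidean
#' distances are computed, so descriptors on very different scales (e.g.,
#' surface area vs. dipole moment) contribute comparably. The training set is
#' seeded with the pair of analytes at maximal distance, then grown by
#' repeatedly adding the candidate whose minimum distance to the selected set
#' is largest, until `round(fraction * n)` analytes are selected. All ties
#' break toward the lowest row index, so identical input always yields an
#' identical split.
#'
#' @param ds A [retention_dataset()].
#' @param fraction Training fraction in (0, 1); default 0.70 (a 70/30 split).
#'
#' @return An object of class `ks_split`: list with integer index vectors
#'   `train` and `validation` (each sorted ascending) and the `fraction`.
#' @export
#' @examples
#' ds <- retention_dataset(letters[1:4],
#'                         matrix(c(0, 1, 2, 10), ncol = 1), c(1, 2, 3, 4))
#' # seeds with the extreme pair (rows 1, 4), then adds the farthest candidate
#' kennard_stone_split(ds, fraction = 0.75)$train  # 1 3 4
kennard_stone_split <- function(ds, fraction = 0.70) {
  stopifnot(inherits(ds, "retention_dataset"))
  n <- n_analytes(ds)
  K <- n_descriptors(ds)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n < 4) stop("need at least 4 analytes to split", call. = FALSE)
  n_train <- round(fraction * n)
  if (n_train < K + 2) {
    stop("training fraction too small: ", n_train, " rows cannot support ",
         K, " coefficients (need at least K + 2 = ", K + 2, ")", call. = FALSE)
  }
  if (n_train >= n) {
    stop("training fraction leaves no validation analytes", call. = FALSE)
  }

  sds <- apply(ds$X, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var)) {
    stop("descriptor column(s) with zero variance cannot be autoscaled: ",
         paste(colnames(ds$X)[zero_var], collapse = ", "), call. = FALSE)
  }
  Z <- scale(ds$X)
  dmat <- as.matrix(stats::dist(Z))

  # seed: the globally most distant pair; among ties, the lexicographically
  # smallest (i, j) with i < j
  upper <- dmat
  upper[lower.tri(upper, diag = TRUE)] <- -Inf
  hits <- which(upper == max(upper), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  selected <- as.integer(hits[1, ])

  while (length(selected) < n_train) {
    remaining <- setdiff(seq_len(n), selected)
    # min distance of each candidate to the selected set
    mind <- apply(dmat[remaining, selected, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)]   # which.max takes the first maximum
    selected <- c(selected, pick)
  }
  train <- sort(as.integer(selected))
  structure(
    list(train = train,
         validation = setdiff(seq_len(n), train),
         fraction = fraction),
    class = "ks_split"
  )
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d training / %d validation (fraction %.2f)\n",
              length(x$train), length(x$validation), x$fraction))
  invisible(x)
}

#' Write a split as a two-column CSV (id, subset)
#'
#' @param ds The [retention_dataset()] that was split.
#' @param split A `ks_split` from [kennard_stone_split()].
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_split <- function(ds, split, path) {
  stopifnot(inherits(ds, "retention_dataset"), inherits(split, "ks_split"))
  subset <- rep("validation", n_analytes(ds))
  subset[split$train] <- "training"
  out <- data.frame(id = ds$ids, subset = subset, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(out)
}
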