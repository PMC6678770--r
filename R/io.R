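#' Read a retention-descriptor table from CSV
#'
#' Expects a comma-separated file with a header row, "." as decimal
#' separator, UTF-8 encoded: one identifier column, one retention-time column
#' (minutes), and one or more numeric descriptor columns. Row order is
#' preserved as read.
#'
#' @param path Path to the CSV file.
#' @param id_col Name of the identifier column (default `"id"`).
#' @param rt_col Name of the retention-time column (default `"tR"`).
#' @param descriptor_cols Character vector naming the descriptor columns.
#'   Defaults to every column other than `id_col` and `rt_col`.
#' @param condition A [chromatographic_condition()] attached to the dataset.
#'
#' @return A validated [retention_dataset()].
#' @export
read_retention_table <- function(path, id_col = "id", rt_col = "tR",
                                 descriptor_cols = NULL,
                                 condition = chromatographic_condition()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!id_col %in% names(tab)) {
    stop("schema error: id column '", id_col, "' not found in ", path, call. = FALSE)
  }
  if (!rt_col %in% names(tab)) {
    stop("schema error: retention column '", rt_col, "' not found in ", path,
         call. = FALSE)
  }
  if (is.null(descriptor_cols)) {
    descriptor_cols <- setdiff(names(tab), c(id_col, rt_col))
  }
  missing_cols <- setdiff(descriptor_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("schema error: descriptor column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(descriptor_cols) < 1) {
    stop("schema error: no descriptor columns", call. = FALSE)
  }
  ids <- as.character(tab[[id_col]])
  num_cols <- c(rt_col, descriptor_cols)
  for (cn in num_cols) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("parse error: non-numeric value in column '", cn, "' for analyte '",
             ids[bad[1]], "'", call. = FALSE)
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop("parse error: missing value in column '", cn, "' for analyte '",
           ids[which(is.na(v))[1]], "'", call. = FALSE)
    }
    tab[[cn]] <- v
  }
  X <- as.matrix(tab[descriptor_cols])
  retention_dataset(ids, X, tab[[rt_col]],
                    descriptor_names = descriptor_cols, condition = condition)
}

#' Write experimental and predicted retention with elution ranks
#'
#' Emits a CSV with columns `id`, `tR_exp`, `tR_pred`, `rank_exp`,
#' `rank_pred`. Ranks are computed over the analytes in `ds` (ranking is
#' relative to the set being written). Values are written with 10 significant
#' digits so a round trip preserves them well beyond 6 significant digits.
#'
#' @param ds A [retention_dataset()].
#' @param y_pred Numeric vector of predicted retention times, same length as
#'   `ds$y`.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(ds, y_pred, path) {
  stopifnot(inherits(ds, "retention_dataset"))
  y_pred <- as.numeric(y_pred)
  if (length(y_pred) != n_analytes(ds)) {
    stop("'y_pred' must have one prediction per analyte (", n_analytes(ds),
         " expected, ", length(y_pred), " given)", call. = FALSE)
  }
  out <- data.frame(
    id = ds$ids,
    tR_exp = signif(ds$y, 10),
    tR_pred = signif(y_pred, 10),
    rank_exp = elution_ranks(ds$y),
    rank_pred = elution_ranks(y_pred),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(out)
}
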