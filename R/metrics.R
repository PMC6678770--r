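#' Percentage root-mean-square error of relative residuals
#'
#' `%RMSE = sqrt(mean(((yhat - y) / y)^2)) * 100`. Each residual is scaled
#' by its own experimental value, so the metric is invariant to a common
#' rescaling of both vectors and late-eluting analytes do not dominate.
#' Values above 100% are possible when predictions are badly off relative to
#' small experimental values.
#'
#' @param y_true Experimental values (all non-zero).
#' @param y_pred Predicted values, same length.
#' @return Non-negative percentage.
#' @export
#' @examples
#' percent_rmse(c(10, 20), c(11, 18))  # 10
percent_rmse <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("'y_true' and 'y_pred' must have the same length", call. = FALSE)
  }
  if (any(y_true == 0)) {
    stop("relative error undefined: 'y_true' contains zero(s)", call. = FALSE)
  }
  sqrt(mean(((y_pred - y_true) / y_true)^2)) * 100
}

#' Percentage RMSE of elution order
#'
#' The relative-error %RMSE with the analyte's elution rank in place of its
#' retention time: `sqrt(mean(((rank_pred - rank_true)/rank_true)^2)) * 100`.
#' Because ranks are 1-based the denominator is never zero; misplacing an
#' early-eluting analyte costs far more than misplacing a late one, and
#' values above 100% occur for badly scrambled orders.
#'
#' @param true_ranks Integer permutation of 1..n (experimental order).
#' @param pred_ranks Integer permutation of 1..n (predicted order).
#' @return Non-negative percentage.
#' @export
#' @examples
#' percent_rmse_order(1:3, c(1, 3, 2))  # ~34.69
percent_rmse_order <- function(true_ranks, pred_ranks) {
  .check_permutation(true_ranks, "true_ranks")
  .check_permutation(pred_ranks, "pred_ranks")
  if (length(true_ranks) != length(pred_ranks)) {
    stop("rank vectors must have the same length", call. = FALSE)
  }
  percent_rmse(true_ranks, pred_ranks)
}

.check_permutation <- function(r, what) {
  r <- as.numeric(r)
  if (anyNA(r) || !isTRUE(all.equal(sort(r), seq_along(r)))) {
    stop("'", what, "' must be a permutation of 1..n", call. = FALSE)
  }
}

#' Count adjacent elution-order inversions
#'
#' Given predictions for analytes ordered by ascending experimental
#' retention time, counts the adjacent pairs predicted out of order
#' (`yhat_j > yhat_{j+1}`) -- the number of violated order constraints at
#' zero relaxation.
#'
#' @param y_pred_on_sorted Predictions ordered by ascending experimental t_R.
#' @return Integer in `0 .. n-1`.
#' @export
count_adjacent_inversions <- function(y_pred_on_sorted) {
  y <- as.numeric(y_pred_on_sorted)
  if (length(y) < 2) return(0L)
  sum(diff(y) < 0)
}

#' Performance metrics of a fitted model on a split dataset
#'
#' Computes %RMSE of retention time and of elution order for the training
#' subset, the validation subset and both combined, plus the count of
#' adjacent order inversions on the training set (sorted by experimental
#' t_R). Predicted ranks are always computed within the subset being scored,
#' since elution order is relative to the analytes in a run.
#'
#' @param model A `qsrr_model`.
#' @param ds The full [retention_dataset()].
#' @param split A `ks_split` from [kennard_stone_split()].
#' @return An object of class `metrics_report`: list with named numeric
#'   vectors `pct_rmse_tr` and `pct_rmse_order` (elements `training`,
#'   `validation`, `combined`), `adjacent_inversions`, and `n_per_subset`.
#' @export
metrics_report <- function(model, ds, split) {
  stopifnot(inherits(model, "qsrr_model"),
            inherits(ds, "retention_dataset"),
            inherits(split, "ks_split"))
  subsets <- list(training = split$train,
                  validation = split$validation,
                  combined = seq_len(n_analytes(ds)))
  tr <- ord <- stats::setNames(numeric(3), names(subsets))
  for (nm in names(subsets)) {
    part <- subset_dataset(ds, subsets[[nm]])
    yhat <- predict(model, part)
    tr[nm] <- percent_rmse(part$y, yhat)
    ord[nm] <- percent_rmse_order(elution_ranks(part$y), elution_ranks(yhat))
  }
  train_sorted <- sort_by_retention(subset_dataset(ds, split$train))
  structure(
    list(pct_rmse_tr = tr,
         pct_rmse_order = ord,
         adjacent_inversions = count_adjacent_inversions(
           predict(model, train_sorted)),
         n_per_subset = vapply(subsets, length, integer(1)),
         kind = model$kind),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (%s model)\n", x$kind))
  tab <- rbind(`%RMSE(tR)` = x$pct_rmse_tr,
               `%RMSE(order)` = x$pct_rmse_order,
               n = x$n_per_subset)
  print(round(tab, 2))
  cat("Adjacent training inversions:", x$adjacent_inversions, "\n")
  invisible(x)
}

#' Flatten a metrics report to a tidy data frame
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Data frame with columns `subset`, `metric`, `value`.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(
    subset = rep(names(x$pct_rmse_tr), 2),
    metric = rep(c("pct_rmse_tr", "pct_rmse_order"),
                 each = length(x$pct_rmse_tr)),
    value = c(unname(x$pct_rmse_tr), unname(x$pct_rmse_order)),
    stringsAsFactors = FALSE
  )
}
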