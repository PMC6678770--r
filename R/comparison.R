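#' Load a model-performance result table
#'
#' Reads (or validates) a long-format table of per-condition model
#' performances with columns `case_study`, `column_name`, `gradient_time_min`,
#' `temperature_C`, `model` (`"MLR"` or `"MLR-NLP"`), `pct_rmse_tr`,
#' `pct_rmse_order`. Every (column, condition) pair must appear exactly once
#' per model.
#'
#' @param path CSV path, or `NULL` to load the bundled case-study summary
#'   (see [case_study_performance()]).
#' @return A validated data frame of class `qsrr_result_table`.
#' @export
read_result_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_result_table(tab)
}

#' @rdname read_result_table
#' @param tab A data frame in the layout above.
#' @export
validate_result_table <- function(tab) {
  needed <- c("case_study", "column_name", "gradient_time_min",
              "temperature_C", "model", "pct_rmse_tr", "pct_rmse_order")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("result table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$model %in% c("MLR", "MLR-NLP"))) {
    stop("'model' must be \"MLR\" or \"MLR-NLP\"", call. = FALSE)
  }
  if (any(tab$pct_rmse_tr < 0) || any(tab$pct_rmse_order < 0)) {
    stop("%RMSE values must be >= 0", call. = FALSE)
  }
  key <- interaction(tab$case_study, tab$column_name, tab$gradient_time_min,
                     tab$temperature_C, drop = TRUE)
  counts <- table(key, tab$model)
  if (!all(counts == 1)) {
    stop("each (column, condition) must have exactly one MLR and one MLR-NLP row",
         call. = FALSE)
  }
  class(tab) <- c("qsrr_result_table", "data.frame")
  tab
}

#' Bundled case-study performance summary
#'
#' Per-condition %RMSE of retention time and elution order for the MLR
#' control and order-constrained models over two published reversed-phase
#' case studies: 62 organic molecules on a Supelcosil LC-18 column, and 98
#' synthetic peptides on seven columns under varied gradient times and
#' temperatures -- 19 condition pairs in all. The underlying retention and
#' descriptor data are not redistributable; only these summary values are
#' shipped, and they drive the paired model comparison.
#'
#' @return A `qsrr_result_table` data frame with 38 rows.
#' @export
#' @examples
#' perf <- case_study_performance()
#' nrow(perf)  # 38
case_study_performance <- function() {
  path <- system.file("extdata", "case_study_performance.csv",
                      package = "qsrrorder", mustWork = TRUE)
  read_result_table(path)
}

#' Paired t-test between two matched performance vectors
#'
#' Classic paired t-test `t = mean(a - b) / (sd(a - b)/sqrt(n))` with the
#' descriptive statistics usually tabulated alongside it: per-group means
#' and sample variances (denominator n - 1), the Pearson correlation of the
#' pairs, one- and two-tailed p values, and the critical t values at
#' alpha = 0.05 with n - 1 degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length (n >= 2), matched by position.
#' @return An object of class `paired_t_test`: list with `mean_a`, `mean_b`,
#'   `var_a`, `var_b`, `pearson_r`, `n`, `df`, `t_stat`, `p_one_tail`,
#'   `p_two_tail`, `t_crit_one_tail`, `t_crit_two_tail`.
#' @export
#' @examples
#' perf <- case_study_performance()
#' a <- perf$pct_rmse_tr[perf$model == "MLR"]
#' b <- perf$pct_rmse_tr[perf$model == "MLR-NLP"]
#' paired_t_test(a, b)
paired_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must be paired", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("differences have zero variance; paired t statistic is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  t_stat <- unname(tt$statistic)
  structure(
    list(mean_a = mean(a), mean_b = mean(b),
         var_a = stats::var(a), var_b = stats::var(b),
         pearson_r = stats::cor(a, b),
         n = n, df = n - 1L,
         t_stat = t_stat,
         p_one_tail = tt$p.value / 2,
         p_two_tail = tt$p.value,
         t_crit_one_tail = stats::qt(0.95, n - 1),
         t_crit_two_tail = stats::qt(0.975, n - 1)),
    class = "paired_t_test"
  )
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat("Paired t-test\n")
  cat(sprintf("  Mean                 %10.3f  %10.3f\n", x$mean_a, x$mean_b))
  cat(sprintf("  Variance             %10.2f  %10.2f\n", x$var_a, x$var_b))
  cat(sprintf("  Observations         %10d  %10d\n", x$n, x$n))
  cat(sprintf("  Pearson correlation  %10.3f\n", x$pearson_r))
  cat(sprintf("  df                   %10d\n", x$df))
  cat(sprintf("  t statistic          %10.3f\n", x$t_stat))
  cat(sprintf("  P one-tail           %10.5f   (critical t %.3f)\n",
              x$p_one_tail, x$t_crit_one_tail))
  cat(sprintf("  P two-tail           %10.5f   (critical t %.3f)\n",
              x$p_two_tail, x$t_crit_two_tail))
  invisible(x)
}

#' Relative performance differences between paired models
#'
#' For every (column, condition) pair computes the percentage change of the
#' order-constrained model relative to the MLR control,
#' `100 * (NLP - MLR) / MLR`, for both %RMSE(t_R) and %RMSE(order), and
#' averages those per-condition changes across conditions (the mean of the
#' relative changes, not the relative change of the means). A positive mean
#' for retention time alongside a negative mean for elution order is the
#' expected trade-off: retention accuracy is sacrificed for order accuracy.
#'
#' @param tab A `qsrr_result_table` (e.g. [case_study_performance()]).
#' @return List with `per_condition` (data frame: condition key columns plus
#'   `rel_diff_pct_rmse_tr`, `rel_diff_pct_rmse_order`) and scalar means
#'   `mean_rel_diff_tr`, `mean_rel_diff_order`.
#' @export
#' @examples
#' s <- relative_difference_summary(case_study_performance())
#' round(c(s$mean_rel_diff_tr, s$mean_rel_diff_order), 2)
relative_difference_summary <- function(tab) {
  tab <- validate_result_table(as.data.frame(tab))
  keys <- c("case_study", "column_name", "gradient_time_min", "temperature_C")
  mlr <- tab[tab$model == "MLR", ]
  nlp <- tab[tab$model == "MLR-NLP", ]
  merged <- merge(mlr, nlp, by = keys, suffixes = c("_mlr", "_nlp"),
                  sort = FALSE)
  bad <- merged$pct_rmse_tr_mlr == 0 | merged$pct_rmse_order_mlr == 0
  if (any(bad)) {
    stop("relative difference undefined (MLR %RMSE of 0) for condition: ",
         paste(merged$column_name[bad], collapse = ", "), call. = FALSE)
  }
  per <- merged[keys]
  per$rel_diff_pct_rmse_tr <-
    100 * (merged$pct_rmse_tr_nlp - merged$pct_rmse_tr_mlr) / merged$pct_rmse_tr_mlr
  per$rel_diff_pct_rmse_order <-
    100 * (merged$pct_rmse_order_nlp - merged$pct_rmse_order_mlr) / merged$pct_rmse_order_mlr
  list(per_condition = per,
       mean_rel_diff_tr = mean(per$rel_diff_pct_rmse_tr),
       mean_rel_diff_order = mean(per$rel_diff_pct_rmse_order))
}
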