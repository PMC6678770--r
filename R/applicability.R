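#' Leverages of query analytes with respect to a training set
#'
#' Diagonal of the hat (projection) matrix evaluated at the query rows:
#' `h_i = x_i' (X_train' X_train)^-1 x_i`. Both matrices must be centered
#' with the *training* descriptor means (no intercept column), consistent
#' with the mean-centered retention model. A training analyte at the
#' centroid has h = 0; training leverages sum to K and never exceed 1;
#' query rows far outside the training cloud can exceed 1.
#'
#' @param X_train Centered training descriptor matrix (full column rank).
#' @param X_query Centered query descriptor matrix (same K); defaults to
#'   `X_train`.
#' @return Numeric vector of leverages, one per query row.
#' @export
#' @examples
#' Xc <- matrix(c(-1, 0, 1), ncol = 1)
#' leverages(Xc)  # 0.5 0.0 0.5
leverages <- function(X_train, X_query = X_train) {
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  if (ncol(X_query) != ncol(X_train)) {
    stop("'X_query' must have the same number of descriptor columns as 'X_train'",
         call. = FALSE)
  }
  XtX <- crossprod(X_train)
  R <- tryCatch(chol(XtX), error = function(e) {
    stop("X_train' X_train is singular; training descriptors are rank deficient",
         call. = FALSE)
  })
  # h_i = || R^-T x_i ||^2
  V <- forwardsolve(t(R), t(X_query))
  colSums(V^2)
}

#' Critical leverage threshold h*
#'
#' The warning limit of the Williams plot. The default variant is
#' `h* = 3(K - 1)/N`; the conventional chemometric threshold
#' `h* = 3(K + 1)/N` is available via `variant = "k+1"`. With a single
#' descriptor the `"k-1"` variant degenerates to 0 (every analyte is flagged
#' as a leverage outlier); use `"k+1"` in that case.
#'
#' @param N Number of training observations.
#' @param K Number of descriptors.
#' @param variant `"k-1"` (default) or `"k+1"`.
#' @return The threshold h*.
#' @export
#' @examples
#' critical_leverage(43, 3)             # 6/43
#' critical_leverage(43, 3, "k+1")      # 12/43
critical_leverage <- function(N, K, variant = c("k-1", "k+1")) {
  variant <- match.arg(variant)
  if (N <= 0 || K < 1) stop("need N > 0 and K >= 1", call. = FALSE)
  if (variant == "k-1") 3 * (K - 1) / N else 3 * (K + 1) / N
}

#' Standardized residuals of a retention model
#'
#' Raw residuals `y - yhat` divided by the training residual standard
#' deviation stored in the model (computed with K degrees of freedom
#' consumed). For a numerically perfect fit the spread is zero; residuals
#' are then reported as 0 with a warning rather than NaN.
#'
#' @param model A `qsrr_model`.
#' @param ds A [retention_dataset()] (training, validation, or any query set).
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(model, ds) {
  stopifnot(inherits(model, "qsrr_model"), inherits(ds, "retention_dataset"))
  res <- ds$y - predict(model, ds)
  s <- model$train_residual_sd
  if (!is.finite(s) || s <= 1e-10 * max(1, abs(model$y_mean))) {
    warning("zero training residual spread (perfect fit); ",
            "standardized residuals reported as 0")
    return(rep(0, length(res)))
  }
  res / s
}

#' Applicability-domain report (Williams plot data)
#'
#' Assembles per-analyte leverage and standardized residual for the training
#' and validation subsets, both computed relative to the training set: the
#' descriptor matrices are centered with the training means and leverages
#' use the training `(X'X)^-1`. An analyte is inside the applicability
#' domain when its leverage is at most the critical value h* and its
#' standardized residual lies within +/- `residual_limit` (3 standard
#' deviations by default).
#'
#' @param model A `qsrr_model` fitted on `train`.
#' @param train Training [retention_dataset()].
#' @param validation Validation [retention_dataset()] (may have 0 rows in
#'   which case only training analytes are reported).
#' @param variant Critical-leverage variant, see [critical_leverage()].
#' @param residual_limit Warning limit on |standardized residual| (default 3).
#' @return An object of class `ad_report`: a data frame with columns `id`,
#'   `subset`, `leverage`, `std_residual`, `in_domain`, and attributes
#'   `critical_leverage` and `residual_limit`.
#' @export
williams_report <- function(model, train, validation = NULL,
                            variant = c("k-1", "k+1"), residual_limit = 3) {
  stopifnot(inherits(model, "qsrr_model"), inherits(train, "retention_dataset"))
  variant <- match.arg(variant)
  K <- n_descriptors(train)
  N <- n_analytes(train)
  hstar <- critical_leverage(N, K, variant)

  Xc_train <- sweep(train$X, 2, model$x_means)
  parts <- list(training = list(ds = train, Xc = Xc_train))
  if (!is.null(validation) && n_analytes(validation) > 0) {
    parts$validation <- list(ds = validation,
                             Xc = sweep(validation$X, 2, model$x_means))
  }
  rows <- lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    data.frame(id = p$ds$ids,
               subset = nm,
               leverage = leverages(Xc_train, p$Xc),
               std_residual = standardized_residuals(model, p$ds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$in_domain <- out$leverage <= hstar & abs(out$std_residual) <= residual_limit
  rownames(out) <- NULL
  structure(out, class = c("ad_report", "data.frame"),
            critical_leverage = hstar, residual_limit = residual_limit,
            variant = variant)
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("Applicability domain: h* = %.4f (%s variant), |residual| limit %g\n",
              attr(x, "critical_leverage"), attr(x, "variant"),
              attr(x, "residual_limit")))
  n_out <- sum(!x$in_domain)
  cat(sprintf("%d of %d analytes outside the domain\n", n_out, nrow(x)))
  NextMethod()
  invisible(x)
}
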