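#' Configuration of the order-constrained fit
#'
#' @param lambda_weight Non-negative weight on the sum of order-relaxation
#'   variables in the objective (default 1, the unweighted sum). Units
#'   caveat: the squared-error term is in min^2 while the relaxation sum is
#'   in min, so `lambda_weight` carries units of minutes and its natural
#'   scale depends on the dataset.
#' @param solver_tolerance Interior-point convergence tolerance (default 1e-8).
#' @param max_iterations Iteration cap for the solver (default 1000).
#' @return An object of class `nlp_config`.
#' @export
nlp_config <- function(lambda_weight = 1, solver_tolerance = 1e-8,
                       max_iterations = 1000) {
  if (!is.numeric(lambda_weight) || lambda_weight < 0) {
    stop("'lambda_weight' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(solver_tolerance) || solver_tolerance <= 0) {
    stop("'solver_tolerance' must be > 0", call. = FALSE)
  }
  structure(list(lambda_weight = lambda_weight,
                 solver_tolerance = solver_tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "nlp_config")
}

# Center training data; error (naming columns) on rank deficiency.
.center_and_check <- function(ds) {
  m <- n_analytes(ds)
  K <- n_descriptors(ds)
  if (m < K + 2) {
    stop("need at least K + 2 = ", K + 2, " training analytes to fit ",
         K, " coefficients", call. = FALSE)
  }
  x_means <- colMeans(ds$X)
  y_mean <- mean(ds$y)
  Xc <- sweep(ds$X, 2, x_means)
  qrX <- qr(Xc)
  if (qrX$rank < K) {
    dropped <- colnames(ds$X)[qrX$pivot[(qrX$rank + 1):K]]
    stop("descriptor matrix is rank deficient after centering; ",
         "collinear column(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  list(Xc = Xc, yc = ds$y - y_mean, x_means = x_means, y_mean = y_mean,
       m = m, K = K)
}

.new_qsrr_model <- function(coefficients, centered, kind, alphas,
                            lambda_weight, solver_status, residuals) {
  K <- centered$K
  sse <- sum(residuals^2)
  structure(
    list(coefficients = stats::setNames(as.numeric(coefficients),
                                        names(centered$x_means)),
         x_means = centered$x_means,
         y_mean = centered$y_mean,
         kind = kind,
         alphas = as.numeric(alphas),
         lambda_weight = lambda_weight,
         solver_status = solver_status,
         sse = sse,
         train_residual_sd = if (centered$m > K) sqrt(sse / (centered$m - K)) else 0),
    class = "qsrr_model"
  )
}

#' Fit the control MLR retention model
#'
#' Ordinary least squares on mean-centered descriptors and retention times:
#' the model is `t_R = y_mean + sum_i a_i (x_i - mean(x_i))`, with no free
#' intercept term beyond the centering means. This is the "control" model
#' against which the order-constrained fit is compared.
#'
#' @param train A [retention_dataset()] of training analytes (at least
#'   K + 2 rows, full column rank after centering).
#' @return An object of class `qsrr_model` with `kind = "MLR"`.
#' @export
#' @examples
#' ds <- retention_dataset(letters[1:5], matrix(1:5, ncol = 1), c(2, 4, 6, 8, 10))
#' fit_mlr(ds)$coefficients  # slope 2
fit_mlr <- function(train) {
  stopifnot(inherits(train, "retention_dataset"))
  cen <- .center_and_check(train)
  fit <- stats::lm.fit(cen$Xc, cen$yc)
  a <- fit$coefficients
  .new_qsrr_model(a, cen, kind = "MLR", alphas = numeric(0),
                  lambda_weight = 0,
                  solver_status = list(converged = TRUE,
                                       objective = sum(fit$residuals^2),
                                       iterations = 0L),
                  residuals = fit$residuals)
}

#' Fit the order-constrained retention model
#'
#' Minimizes the sum of squared retention-time errors plus
#' `lambda_weight` times the sum of non-negative relaxation variables
#' `alpha_j`, subject to the relaxed elution-order constraints
#' `yhat_j - yhat_{j+1} <= alpha_j` over the m - 1 adjacent pairs of the
#' training set sorted by ascending experimental retention time. Each
#' `alpha_j` is the price paid for predicting pair j out of order (a hinge
#' penalty); with all constraints inactive the fit coincides with
#' [fit_mlr()]. The problem is a convex quadratic program and is solved with
#' the primal-dual interior-point method of [solve_qp_interior_point()],
#' warm-started at the ordinary least-squares solution.
#'
#' @param train A [retention_dataset()] of training analytes. Rows are
#'   sorted internally by experimental retention time (stable) before the
#'   constraints are built; the input order does not matter.
#' @param config An [nlp_config()].
#' @return An object of class `qsrr_model` with `kind = "MLR-NLP"`, the
#'   fitted relaxations in `$alphas` (ordered along the sorted training
#'   set), and solver diagnostics in `$solver_status`.
#' @export
fit_order_constrained <- function(train, config = nlp_config()) {
  stopifnot(inherits(train, "retention_dataset"),
            inherits(config, "nlp_config"))
  train <- sort_by_retention(train)
  cen <- .center_and_check(train)
  m <- cen$m; K <- cen$K
  lam <- config$lambda_weight
  Xc <- cen$Xc; yc <- cen$yc

  a_ols <- qr.solve(Xc, yc)
  if (m < 2) {   # no adjacent pairs: OLS is the solution
    res <- yc - as.numeric(Xc %*% a_ols)
    return(.new_qsrr_model(a_ols, cen, "MLR-NLP", numeric(0), lam,
                           list(converged = TRUE, objective = sum(res^2),
                                iterations = 0L), res))
  }

  # Differences of adjacent (sorted) descriptor rows: yhat_j - yhat_{j+1}
  # equals D[j, ] %*% a because centering cancels in the difference.
  D <- Xc[-m, , drop = FALSE] - Xc[-1, , drop = FALSE]

  # If OLS already respects every adjacent order constraint it is the exact
  # optimum of the penalized problem (it minimizes the SSE term globally and
  # contributes zero penalty), so no solve is needed.
  if (all(D %*% a_ols <= 0)) {
    res <- yc - as.numeric(Xc %*% a_ols)
    return(.new_qsrr_model(a_ols, cen, "MLR-NLP", rep(0, m - 1), lam,
                           list(converged = TRUE, objective = sum(res^2),
                                iterations = 0L), res))
  }

  nv <- K + (m - 1)
  Q <- matrix(0, nv, nv)
  Q[1:K, 1:K] <- 2 * crossprod(Xc)
  qvec <- c(-2 * crossprod(Xc, yc), rep(lam, m - 1))
  G <- rbind(cbind(D, -diag(m - 1)),
             cbind(matrix(0, m - 1, K), -diag(m - 1)))
  h <- rep(0, 2 * (m - 1))
  z0 <- c(a_ols, pmax(0, as.numeric(D %*% a_ols)) + 1)

  sol <- solve_qp_interior_point(Q, qvec, G, h, z0 = z0,
                                 tol = config$solver_tolerance,
                                 max_iterations = config$max_iterations)
  if (!sol$converged) {
    stop("interior-point solver did not converge (", sol$iterations,
         " iterations, complementarity gap ", format(sol$gap), ")",
         call. = FALSE)
  }
  a <- sol$z[1:K]
  alphas <- pmax(sol$z[(K + 1):nv], 0)   # clip solver-level negatives ~ -1e-12
  res <- yc - as.numeric(Xc %*% a)
  .new_qsrr_model(a, cen, "MLR-NLP", alphas, lam,
                  list(converged = TRUE,
                       objective = sum(res^2) + lam * sum(alphas),
                       iterations = sol$iterations),
                  res)
}

#' Predict retention times
#'
#' Applies the fitted linear model on the original scale:
#' `yhat = (X - x_means) %*% a + y_mean`.
#'
#' @param object A `qsrr_model`.
#' @param newdata A numeric matrix with K descriptor columns, or a
#'   [retention_dataset()].
#' @param ... Unused.
#' @return Numeric vector of predicted retention times (minutes).
#' @export
predict.qsrr_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "retention_dataset")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop("newdata has ", ncol(X), " descriptor columns but the model expects ",
         length(object$coefficients), call. = FALSE)
  }
  as.numeric(sweep(X, 2, object$x_means) %*% object$coefficients + object$y_mean)
}

#' @export
print.qsrr_model <- function(x, ...) {
  cat(sprintf("QSRR model (%s)\n", x$kind))
  cat("Coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("Training SSE: %.6g min^2", x$sse))
  if (x$kind == "MLR-NLP") {
    cat(sprintf(";  lambda = %g;  sum(alpha) = %.6g min (%d active)",
                x$lambda_weight, sum(x$alphas), sum(x$alphas > 1e-8)))
  }
  cat("\n")
  invisible(x)
}

#' Hinge penalty of a model's order violations on a sorted training set
#'
#' For a dataset sorted by ascending experimental retention time, returns
#' `sum_j max(0, yhat_j - yhat_{j+1})`: the smallest total relaxation that
#' would make the model's predictions feasible for the adjacent elution-order
#' constraints. Zero means the predicted order already respects the
#' experimental order on every adjacent pair.
#'
#' @param model A `qsrr_model`.
#' @param train_sorted A [retention_dataset()] whose rows are already sorted
#'   by non-decreasing experimental retention time (see
#'   [sort_by_retention()]); unsorted input is an error.
#' @return Non-negative scalar (minutes).
#' @export
hinge_order_penalty <- function(model, train_sorted) {
  stopifnot(inherits(model, "qsrr_model"),
            inherits(train_sorted, "retention_dataset"))
  if (is.unsorted(train_sorted$y)) {
    stop("'train_sorted' must be sorted by ascending retention time; ",
         "apply sort_by_retention() first", call. = FALSE)
  }
  yhat <- predict(model, train_sorted)
  sum(pmax(0, -diff(yhat)))
}
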