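#' Primal-dual interior-point solver for convex quadratic programs
#'
#' Solves `min 0.5 z' Q z + q' z  subject to  G z <= h` for positive
#' semidefinite `Q` by Mehrotra's predictor-corrector method. Each iteration
#' eliminates the slack/multiplier block and solves the reduced normal system
#' `(Q + G' W G) dz = r` by Cholesky factorization; a tiny diagonal shift is
#' applied only if the factorization fails numerically. Convergence requires
#' the primal and dual residuals and the complementarity gap to fall below
#' `tol` (dual residual relative to the magnitude of `q`).
#'
#' This is the engine behind [fit_order_constrained()]; it is exported
#' because small order-constrained problems are convenient to probe directly.
#'
#' @param Q Symmetric positive semidefinite matrix (n x n).
#' @param q Numeric vector (length n).
#' @param G Constraint matrix (m x n).
#' @param h Constraint right-hand side (length m).
#' @param z0 Optional starting point; slacks are initialized strictly
#'   positive regardless of feasibility of `z0`.
#' @param tol Convergence tolerance (default 1e-9).
#' @param max_iterations Iteration cap (default 100; typical problems
#'   converge in fewer than 20).
#'
#' @return List with `z` (solution), `lambda` (inequality multipliers),
#'   `iterations`, `converged` (logical), and `gap` (final mean
#'   complementarity).
#' @export
#' @examples
#' # min (z1 - 1)^2 + (z2 - 2)^2 s.t. z1 + z2 <= 2  -> z = (0.5, 1.5)
#' sol <- solve_qp_interior_point(diag(2) * 2, c(-2, -4),
#'                                matrix(c(1, 1), 1, 2), 2)
#' round(sol$z, 6)
solve_qp_interior_point <- function(Q, q, G, h, z0 = NULL,
                                    tol = 1e-9, max_iterations = 100) {
  Q <- as.matrix(Q); G <- as.matrix(G)
  q <- as.numeric(q); h <- as.numeric(h)
  n <- length(q); m <- nrow(G)
  stopifnot(nrow(Q) == n, ncol(Q) == n, ncol(G) == n, length(h) == m)
  if (m == 0) {   # unconstrained: single linear solve
    z <- solve(Q, -q)
    return(list(z = as.numeric(z), lambda = numeric(0), iterations = 0L,
                converged = TRUE, gap = 0))
  }
  z <- if (is.null(z0)) rep(0, n) else as.numeric(z0)
  s <- pmax(h - as.numeric(G %*% z), 1)
  lam <- rep(1, m)
  qscale <- max(1, max(abs(q)))

  max_step <- function(v, dv) {
    neg <- dv < 0
    if (!any(neg)) 1 else min(1, min(-v[neg] / dv[neg]))
  }

  for (it in seq_len(max_iterations)) {
    rd <- as.numeric(Q %*% z + q + crossprod(G, lam))
    rp <- as.numeric(G %*% z + s - h)
    mu <- sum(s * lam) / m
    if (max(abs(rd)) < tol * qscale && max(abs(rp)) < tol && mu < tol) {
      return(list(z = z, lambda = lam, iterations = it - 1L,
                  converged = TRUE, gap = mu))
    }
    W <- lam / s
    M <- Q + crossprod(G, G * W)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) {
      M <- M + diag(1e-12 * max(diag(M)), n)
      R <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(R)) break
    }
    newton <- function(corr) {
      rhs <- -rd + as.numeric(crossprod(G, lam - W * rp - corr / s))
      dz <- backsolve(R, forwardsolve(t(R), rhs))
      ds <- as.numeric(-rp - G %*% dz)
      dlam <- as.numeric(-lam - W * ds + corr / s)
      list(dz = dz, ds = ds, dlam = dlam)
    }
    aff <- newton(rep(0, m))
    a_aff <- min(max_step(s, aff$ds), max_step(lam, aff$dlam))
    mu_aff <- sum((s + a_aff * aff$ds) * (lam + a_aff * aff$dlam)) / m
    sigma <- (mu_aff / mu)^3
    cc <- newton(sigma * mu - aff$ds * aff$dlam)
    alpha <- 0.995 * min(max_step(s, cc$ds), max_step(lam, cc$dlam))
    z <- z + alpha * cc$dz
    s <- s + alpha * cc$ds
    lam <- lam + alpha * cc$dlam
  }
  list(z = z, lambda = lam, iterations = max_iterations,
       converged = FALSE, gap = sum(s * lam) / m)
}
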