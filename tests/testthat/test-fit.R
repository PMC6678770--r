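test_that("MLR recovers closed-form least-squares coefficients", {
  # centered x = (-1, 0, 1), y = (-1, 0, 1): slope exactly 1
  m <- fit_mlr(tiny_dataset(c(4, 5, 6), c(9, 10, 11)))
  expect_equal(unname(m$coefficients), 1, tolerance = 1e-12)

  # centered x = (-1, 1, 0), y = (-1, 0, 1): slope = sum(xc*yc)/sum(xc^2) = 0.5
  m2 <- fit_mlr(worked_instance())
  expect_equal(unname(m2$coefficients), 0.5, tolerance = 1e-12)

  # constant response: zero coefficients
  m3 <- fit_mlr(tiny_dataset(c(1, 2, 3), c(5, 5, 5)))
  expect_equal(unname(m3$coefficients), 0, tolerance = 1e-12)
})

test_that("rank-deficient descriptors are rejected by name", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = 2 * c(1, 2, 3, 4, 5))
  ds <- retention_dataset(letters[1:5], X, c(1, 2, 3, 4, 5))
  expect_error(fit_mlr(ds), "rank deficient")
  expect_error(fit_order_constrained(ds), "rank deficient")
})

test_that("the worked order-constrained instance matches its closed form and a grid oracle", {
  ds <- worked_instance()
  fit <- fit_order_constrained(ds, nlp_config(lambda_weight = 1))
  expect_equal(unname(fit$coefficients), 0.25, tolerance = 1e-6)
  expect_equal(fit$alphas, c(0, 0.25), tolerance = 1e-6)
  expect_equal(fit$solver_status$objective, 1.875, tolerance = 1e-6)

  cs <- centered_sorted(ds)
  grid <- seq(-2, 2, by = 1e-4)
  vals <- vapply(grid, reduced_objective, numeric(1), Xc = cs$Xc, yc = cs$yc,
                 lambda = 1)
  expect_equal(grid[which.min(vals)], 0.25, tolerance = 1e-3)
  expect_equal(min(vals), 1.875, tolerance = 1e-6)
})

test_that("lambda = 0 and order-respecting data both recover plain MLR", {
  ds <- worked_instance()
  fit0 <- fit_order_constrained(ds, nlp_config(lambda_weight = 0))
  expect_equal(fit0$coefficients, fit_mlr(ds)$coefficients, tolerance = 1e-6)

  # strictly monotone response: OLS already respects order, constraints idle
  ds_mono <- tiny_dataset(1:8, 2 * (1:8) + 1)
  fit_m <- fit_order_constrained(ds_mono)
  expect_equal(fit_m$coefficients, fit_mlr(ds_mono)$coefficients,
               tolerance = 1e-6)
  expect_lt(max(fit_m$alphas), 1e-6)
})

test_that("prediction is the centered linear map on the original scale", {
  ds <- tiny_dataset(c(4, 5, 6), c(9, 10, 11))
  m <- fit_mlr(ds)
  expect_equal(predict(m, ds), ds$y, tolerance = 1e-10)

  m_const <- fit_mlr(tiny_dataset(c(1, 2, 3), c(5, 5, 5)))
  expect_equal(predict(m_const, matrix(c(-10, 40), ncol = 1)), c(5, 5),
               tolerance = 1e-10)

  # hand-computed 2x2 product: yhat = (X - means) a + y_mean
  m$coefficients[] <- 2
  m$x_means[] <- 1
  m$y_mean <- 10
  X <- matrix(c(3, -2), ncol = 1)
  expect_equal(predict(m, X), c((3 - 1) * 2 + 10, (-2 - 1) * 2 + 10),
               tolerance = 1e-12)
  expect_error(predict(m, matrix(1, 1, 2)), "descriptor columns")
})

test_that("hinge_order_penalty totals the positive adjacent gaps", {
  ds <- tiny_dataset(1:6, c(1, 2, 3, 4, 5, 6))
  asc <- fit_mlr(ds)
  expect_equal(hinge_order_penalty(asc, ds), 0)

  # OLS on the worked instance predicts (-0.5, 0.5, 0) centered: one hinge 0.5
  w <- worked_instance()
  expect_equal(hinge_order_penalty(fit_mlr(w), sort_by_retention(w)), 0.5,
               tolerance = 1e-12)

  # reversing a strictly ascending prediction telescopes to the full span
  m <- fit_mlr(ds)
  m$coefficients[] <- -m$coefficients  # predictions now strictly descending
  yhat <- predict(m, ds)
  expect_equal(hinge_order_penalty(m, ds), sum(-diff(yhat)), tolerance = 1e-12)
  expect_equal(hinge_order_penalty(m, ds), yhat[1] - yhat[6], tolerance = 1e-12)

  expect_error(hinge_order_penalty(asc, tiny_dataset(1:3, c(3, 1, 2))),
               "sorted")
})

test_that("order-constrained fits trade retention error for order error, never the reverse", {
  suite <- make_benchmark_suite(n_instances = 30, seed = 17)
  for (ds in suite) {
    train <- sort_by_retention(ds)
    mlr <- fit_mlr(train)
    nlp <- fit_order_constrained(train)
    sse <- function(m) sum((train$y - predict(m, train))^2)
    expect_gte(sse(nlp), sse(mlr) - 1e-6)
    expect_lte(hinge_order_penalty(nlp, train),
               hinge_order_penalty(mlr, train) + 1e-6)
    # optimality: constrained objective never exceeds the OLS point's value
    expect_lte(sse(nlp) + sum(nlp$alphas),
               sse(mlr) + hinge_order_penalty(mlr, train) + 1e-6)
    # no slack beyond the hinge: alpha_j = max(0, yhat_j - yhat_{j+1})
    yhat <- predict(nlp, train)
    expect_equal(nlp$alphas, pmax(0, -diff(yhat)), tolerance = 1e-5)
  }
})

test_that("the solver agrees with an independent interior-point QP implementation", {
  library(kernlab)
  set.seed(28)
  for (i in 1:5) {
    ds <- simulate_retention_dataset(n_analytes = 15, seed = 100 + i,
                                     warp_strength = 1, noise_sd = 0.5)
    cs <- centered_sorted(ds)
    Xc <- cs$Xc; yc <- cs$yc
    m <- nrow(Xc); K <- ncol(Xc); lam <- 1
    fit <- fit_order_constrained(cs$ds)

    D <- Xc[-m, , drop = FALSE] - Xc[-1, , drop = FALSE]
    nv <- K + m - 1
    H <- matrix(0, nv, nv); H[1:K, 1:K] <- 2 * crossprod(Xc)
    cc <- c(-2 * crossprod(Xc, yc), rep(lam, m - 1))
    A <- cbind(D, -diag(m - 1))
    sol <- kernlab::ipop(cc, H, A, b = rep(-1e3, m - 1),
                         l = c(rep(-50, K), rep(0, m - 1)), u = rep(50, nv),
                         r = rep(1e3, m - 1), sigf = 8, maxiter = 200)
    expect_equal(kernlab::how(sol), "converged")
    a_ipop <- kernlab::primal(sol)[1:K]
    f_pkg <- reduced_objective(unname(fit$coefficients), Xc, yc, lam)
    f_ipop <- reduced_objective(a_ipop, Xc, yc, lam)
    expect_equal(f_pkg, f_ipop, tolerance = 1e-5)
    expect_lte(f_pkg, f_ipop + 1e-6)
  }
})

test_that("increasing lambda monotonically tightens order at the cost of fit", {
  ds <- sort_by_retention(simulate_retention_dataset(
    n_analytes = 25, seed = 77, warp_strength = 2, noise_sd = 0.5))
  lambdas <- c(0, 0.25, 1, 4, 16, 64)
  fits <- lapply(lambdas, function(l)
    fit_order_constrained(ds, nlp_config(lambda_weight = l)))
  hinges <- vapply(fits, hinge_order_penalty, numeric(1), train_sorted = ds)
  sses <- vapply(fits, function(m) sum((ds$y - predict(m, ds))^2), numeric(1))
  expect_true(all(diff(hinges) <= 1e-6))
  expect_true(all(diff(sses) >= -1e-6))
  expect_equal(fits[[1]]$coefficients, fit_mlr(ds)$coefficients,
               tolerance = 1e-6)
})
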