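test_that("leverages match the hand-computed hat diagonal", {
  Xc <- matrix(c(-1, 0, 1), ncol = 1)
  expect_equal(leverages(Xc), c(0.5, 0, 0.5), tolerance = 1e-12)
  # a query at the centroid has zero leverage
  expect_equal(leverages(Xc, matrix(0, 1, 1)), 0, tolerance = 1e-12)
})

test_that("training leverages sum to K and stay within [0, 1]", {
  set.seed(13)
  for (K in 1:4) {
    X <- matrix(rnorm(30 * K), 30, K)
    Xc <- sweep(X, 2, colMeans(X))
    h <- leverages(Xc)
    expect_equal(sum(h), K, tolerance = 1e-10)
    expect_true(all(h >= 0 & h <= 1 + 1e-12))
  }
})

test_that("leverage is invariant under rotation of descriptor space", {
  set.seed(14)
  X <- scale(matrix(rnorm(20 * 3), 20, 3), scale = FALSE)
  Qrot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(leverages(X %*% Qrot), leverages(X), tolerance = 1e-10)
})

test_that("critical leverage follows 3(K-1)/N with a conventional 3(K+1)/N variant", {
  expect_equal(critical_leverage(43, 3), 6 / 43)
  expect_equal(critical_leverage(43, 3, "k+1"), 12 / 43)
  expect_equal(critical_leverage(10, 1), 0)  # documented degenerate boundary
  expect_error(critical_leverage(0, 3), "N > 0")
})

test_that("standardized residuals divide by the training residual SD (ddof = K)", {
  ds <- simulate_retention_dataset(n_analytes = 20, seed = 3, noise_sd = 1)
  model <- fit_mlr(ds)
  raw <- ds$y - predict(model, ds)
  s_expected <- sqrt(sum(raw^2) / (20 - 3))
  expect_equal(standardized_residuals(model, ds), raw / s_expected,
               tolerance = 1e-10)

  # perfect fit: flagged, all zeros instead of NaN
  exact <- tiny_dataset(1:5, 2 * (1:5) + 3)
  m0 <- fit_mlr(exact)
  expect_warning(z <- standardized_residuals(m0, exact), "perfect fit")
  expect_equal(z, rep(0, 5))
})

test_that("well-behaved synthetic data falls inside the applicability domain", {
  ds <- simulate_retention_dataset(n_analytes = 40, seed = 8, noise_sd = 0.3)
  sp <- kennard_stone_split(ds)
  train <- subset_dataset(ds, sp$train)
  validation <- subset_dataset(ds, sp$validation)
  model <- fit_order_constrained(train)
  # conventional 3(K+1)/N warning limit: the stricter 3(K-1)/N variant flags
  # the extreme training points that Kennard-Stone deliberately selects
  rep <- williams_report(model, train, validation, variant = "k+1")
  expect_equal(nrow(rep), 40)
  expect_true(all(rep$in_domain))
  expect_equal(attr(rep, "critical_leverage"),
               3 * (3 + 1) / length(sp$train))
})

test_that("leverage and residual outliers are flagged out of domain", {
  ds <- simulate_retention_dataset(n_analytes = 30, seed = 19, noise_sd = 0.5)
  model <- fit_mlr(ds)

  # a query far outside the training descriptor cloud: leverage outlier
  far <- retention_dataset("far_out", matrix(c(25, -25, 25), 1, 3,
                                             dimnames = list(NULL, colnames(ds$X))),
                           y = 12)
  rep <- williams_report(model, ds, far)
  far_row <- rep[rep$id == "far_out", ]
  expect_gt(far_row$leverage, attr(rep, "critical_leverage"))
  expect_false(far_row$in_domain)

  # a 10-SD response outlier: residual outlier at ordinary leverage
  outlier <- subset_dataset(ds, 1)
  outlier$ids <- "shifted"
  outlier$y <- outlier$y + 10 * model$train_residual_sd
  rep2 <- williams_report(model, ds, outlier)
  out_row <- rep2[rep2$id == "shifted", ]
  expect_gt(abs(out_row$std_residual), 3)
  expect_false(out_row$in_domain)
})
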