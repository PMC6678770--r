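test_that("CSV round trip preserves a retention table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,tR,mu,delta_min,SASA",
               "benzene,3.10,0.00,-0.20,110.5",
               "phenol,1.95,1.45,-0.65,104.2",
               "toluene,4.22,0.36,-0.22,127.9"), path)
  ds <- read_retention_table(path)
  expect_equal(n_analytes(ds), 3)
  expect_equal(n_descriptors(ds), 3)
  expect_equal(colnames(ds$X), c("mu", "delta_min", "SASA"))
  expect_equal(ds$ids, c("benzene", "phenol", "toluene"))
  expect_equal(ds$y, c(3.10, 1.95, 4.22))
  expect_equal(unname(ds$X[2, "mu"]), 1.45)
})

test_that("schema and validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,tR,mu", "a,1.0,0.1", "b,2.0,0.2", "c,0.0,0.3"), path)
  expect_error(read_retention_table(path), "> 0")

  writeLines(c("id,tR,mu", "a,1.0,0.1", "a,2.0,0.2"), path)
  expect_error(read_retention_table(path), "duplicate")

  writeLines(c("id,tR,mu", "a,1.0,oops", "b,2.0,0.2"), path)
  expect_error(read_retention_table(path), "non-numeric.*'mu'.*'a'")

  writeLines(c("id,rt,mu", "a,1.0,0.1"), path)
  expect_error(read_retention_table(path), "retention column 'tR'")

  expect_error(read_retention_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("sort_by_retention orders rows by ascending t_R, stably", {
  ds <- tiny_dataset(c(10, 20, 30), c(3.2, 1.1, 2.0))
  expect_equal(sort_by_retention(ds)$ids, c("a02", "a03", "a01"))

  sorted <- tiny_dataset(1:3, c(1, 2, 3))
  expect_identical(sort_by_retention(sorted)$ids, sorted$ids)

  tied <- tiny_dataset(c(1, 2, 3), c(1.0, 1.0, 0.5))
  expect_equal(sort_by_retention(tied)$ids, c("a03", "a01", "a02"))
})

test_that("elution ranks are stable 1-based permutations", {
  expect_equal(elution_ranks(c(3.2, 1.1, 2.0)), c(3L, 1L, 2L))
  expect_equal(elution_ranks(sort(runif(10))), 1:10)
  expect_equal(elution_ranks(c(2.0, 2.0, 1.0)), c(2L, 3L, 1L))
  expect_error(elution_ranks(c(1, NaN)), "finite")

  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    r <- elution_ranks(round(runif(n), 1))  # rounding forces ties
    expect_setequal(r, 1:n)
  }
})

test_that("sorting then ranking yields the identity permutation", {
  set.seed(12)
  for (i in 1:10) {
    ds <- tiny_dataset(rnorm(8), round(runif(8, 1, 5), 1))
    expect_equal(elution_ranks(sort_by_retention(ds)$y), 1:8)
  }
})

test_that("write_predictions round-trips values and ranks", {
  ds <- tiny_dataset(c(1, 2, 3), c(1.234567, 2.345678, 3.456789))
  path <- withr::local_tempfile(fileext = ".csv")

  write_predictions(ds, ds$y, path)
  out <- read.csv(path)
  expect_equal(out$rank_exp, out$rank_pred)

  write_predictions(ds, rev(ds$y), path)
  out <- read.csv(path)
  expect_equal(out$rank_pred, 3:1)

  y_pred <- c(1.111111234, 3.333333987, 2.222222567)
  write_predictions(ds, y_pred, path)
  out <- read.csv(path)
  expect_equal(out$tR_exp, ds$y, tolerance = 1e-7)
  expect_equal(out$tR_pred, y_pred, tolerance = 1e-7)
  expect_equal(out$id, ds$ids)

  expect_error(write_predictions(ds, c(1, 2), path), "per analyte")
})

test_that("dataset invariants are enforced at construction", {
  expect_error(retention_dataset("a", matrix(NA_real_, 1, 1), 1), "missing")
  expect_error(retention_dataset(c("a", "b"), matrix(1:2, 2, 1), c(1, -1)), "> 0")
  expect_error(retention_dataset(c("a", "b"), matrix(1:2, 2, 1), c(1, Inf)),
               "finite")
  expect_error(chromatographic_condition(gradient_time = -5), "gradient_time")
})
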