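# Shared fixtures and independent oracles. Oracles are written with plain
# arithmetic, independent of the package's code paths.

# Three analytes, one descriptor; centered values are x_c = (-1, 1, 0),
# y_c = (-1, 0, 1), the instance whose order-constrained optimum is known in
# closed form (a = 0.25, alpha = (0, 0.25), objective 1.875 at lambda = 1).
worked_instance <- function() {
  retention_dataset(c("p1", "p2", "p3"),
                    matrix(c(4, 6, 5), ncol = 1, dimnames = list(NULL, "x1")),
                    c(9, 10, 11))
}

tiny_dataset <- function(x, y, ids = sprintf("a%02d", seq_along(y))) {
  retention_dataset(ids, matrix(x, ncol = 1, dimnames = list(NULL, "x1")), y)
}

# Reduced objective of the order-constrained problem as a function of the
# coefficient vector alone: SSE plus lambda * sum of hinge terms over
# adjacent pairs of the (already sorted) centered data. Plain loops.
reduced_objective <- function(a, Xc, yc, lambda) {
  m <- nrow(Xc)
  sse <- 0
  for (j in seq_len(m)) sse <- sse + (yc[j] - sum(Xc[j, ] * a))^2
  pen <- 0
  if (m >= 2) {
    for (j in seq_len(m - 1)) {
      gap <- sum(Xc[j, ] * a) - sum(Xc[j + 1, ] * a)
      if (gap > 0) pen <- pen + gap
    }
  }
  sse + lambda * pen
}

# Center a dataset (sorted by y) and return the pieces the oracles need.
centered_sorted <- function(ds) {
  ds <- sort_by_retention(ds)
  list(Xc = sweep(ds$X, 2, colMeans(ds$X)), yc = ds$y - mean(ds$y), ds = ds)
}

# From-scratch paired t-test oracle: formulas only, no stats::t.test.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  sd_d <- sqrt(sum((d - mean(d))^2) / (n - 1))
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, p_two = 2 * stats::pt(-abs(t), n - 1))
}
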