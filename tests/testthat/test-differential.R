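test_that("bh_adjust matches a brute-force BH oracle", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential_test is symmetric and flags known fold changes", {
  set.seed(6)
  base <- matrix(rpois(400, 100), 100, 4)
  x <- make_counts(cbind(base, base), stage = rep(0:1, each = 4))
  ids <- x$samples$sample_id
  # duplicated groups: all fold changes exactly zero, nothing significant
  d <- differential_test(x, ids[1:4], ids[5:8])
  expect_true(all(d$log2fc == 0))
  expect_false(any(d$significant))
  expect_true(all(d$direction == "tie"))

  # doubling all counts gives log2fc = log2((2m+.5)/(m+.5)) exactly
  x2 <- make_counts(cbind(base, 2L * base), stage = rep(0:1, each = 4))
  d2 <- differential_test(x2, ids[1:4], ids[5:8])
  m <- rowMeans(base)
  expect_equal(d2$log2fc, log2((2 * m + 0.5) / (m + 0.5)))

  # antisymmetry under group swap
  set.seed(7)
  xr <- make_counts(matrix(rnbinom(800, mu = 80, size = 8), 100, 8),
                    stage = rep(0:1, each = 4))
  da <- differential_test(xr, ids[1:4], ids[5:8])
  db <- differential_test(xr, ids[5:8], ids[1:4],
                          dispersion = attr(da, "dispersion"))
  expect_equal(da$log2fc, -db$log2fc)
  expect_equal(da$pvalue, db$pvalue)

  expect_error(differential_test(x, character(0), ids[5:8]), "non-empty")
  expect_error(differential_test(x, ids[1:4], ids[4:8]), "disjoint")
})

test_that("NB exact test holds its size on null data", {
  set.seed(8)
  n_p <- 1000
  mu <- exp(rnorm(n_p, log(80), 1))
  counts <- matrix(rnbinom(n_p * 12, mu = rep(mu, 12), size = 1 / 0.15), n_p, 12)
  x <- make_counts(counts, stage = rep(0:1, each = 6))
  ids <- x$samples$sample_id
  d <- differential_test(x, ids[1:6], ids[7:12])
  rate <- mean(d$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / n_p)
  expect_gt(rate, 0.05 - 3 * se)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("NB exact test agrees with edgeR on mixed signal/null data", {
  skip_if_not_installed("edgeR")
  set.seed(9)
  n_p <- 300
  mu <- exp(rnorm(n_p, log(80), 1))
  fc <- ifelse(runif(n_p) < 0.3, 2^rnorm(n_p), 1)
  counts <- cbind(matrix(rnbinom(n_p * 5, mu = rep(mu, 5), size = 10), n_p),
                  matrix(rnbinom(n_p * 5, mu = rep(mu * fc, 5), size = 10), n_p))
  x <- make_counts(counts, stage = rep(0:1, each = 5))
  ids <- x$samples$sample_id
  d <- differential_test(x, ids[1:5], ids[6:10])
  y <- edgeR::DGEList(counts = counts, lib.size = x$samples$library_size,
                      group = rep(c("A", "B"), each = 5))
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)
  expect_gt(cor(d$pvalue, et$table$PValue, method = "spearman"), 0.95)
  expect_gt(cor(d$log2fc, et$table$logFC), 0.95)
})

test_that("three_group_test finds the planted peak and matches aov", {
  set.seed(10)
  n <- 12
  vals <- matrix(rnorm(50 * n, 8, 0.3), 50, n)
  # peak 7: monotone decrease 10 / 8 / 6 with tiny variance
  vals[7, ] <- rep(c(10, 8, 6), each = 4) + rnorm(n, 0, 0.01)
  x <- make_counts(matrix(1L, 50, n), stage = rep(0:2, each = 4))
  nn <- normalize_counts(x)
  dimnames(vals) <- dimnames(nn$values)
  nn$values <- vals
  ids <- x$samples$sample_id
  groups <- list(ids[1:4], ids[5:8], ids[9:12])
  res <- three_group_test(nn, groups)
  expect_true(res$significant[7])
  expect_equal(which(res$significant), 7L)
  expect_equal(res$dir_2_vs_1[7], -1)
  expect_equal(res$dir_3_vs_2[7], -1)

  # identical groups: nothing significant
  same <- nn
  same$values <- cbind(vals[, 1:4], vals[, 1:4], vals[, 1:4])
  colnames(same$values) <- colnames(vals)
  expect_false(any(three_group_test(same, groups)$significant))

  # F p-value matches stats::aov on a single peak
  g <- factor(rep(1:3, each = 4))
  pa <- summary(stats::aov(vals[1, ] ~ g))[[1]][["Pr(>F)"]][1]
  expect_equal(res$pvalue[1], pa, tolerance = 1e-10)

  expect_error(three_group_test(nn, groups[1:2]), "three")
})

test_that("label permutation on null data yields ~no significant peaks", {
  set.seed(11)
  counts <- matrix(rnbinom(500 * 12, mu = 80, size = 8), 500, 12)
  x <- make_counts(counts, stage = rep(0:2, each = 4))
  ids <- sample(x$samples$sample_id)   # permuted labels
  res <- three_group_test(x, list(ids[1:4], ids[5:8], ids[9:12]))
  expect_lte(sum(res$significant), 2L)
})

test_that("global_shift applies the tie convention and bins fold changes", {
  res <- data.frame(peak = paste0("p", 1:4), mean_signal = c(1, 2, 3, 4),
                    log2fc = c(-1, -1, 1, 0))
  gs <- global_shift(res, n_bins = 2)
  expect_equal(gs$frac_reduced, 0.5)
  expect_equal(gs$n_tie, 1L)
  expect_equal(gs$n_increased, 1L)
  expect_equal(sum(gs$mean_fc_curve$n), 4L)
  # all reduced
  res2 <- res; res2$log2fc <- -abs(res2$log2fc) - 0.1
  expect_equal(global_shift(res2)$frac_reduced, 1)
  # invariant to peak order
  sh <- res[sample(4), ]
  expect_equal(global_shift(sh)$frac_reduced, gs$frac_reduced)
  expect_error(global_shift(res, n_bins = 0), "n_bins")
})

test_that("paired_eye_shift compares two samples on normalized signal", {
  set.seed(12)
  x <- make_counts(matrix(rpois(300, 60), 100, 3))
  nn <- normalize_counts(x)
  ids <- x$samples$sample_id
  # identical sample vs itself: only ties
  same <- paired_eye_shift(nn, ids[1], ids[1])
  expect_equal(same$n_reduced, 0L)
  expect_equal(same$n_tie, 100L)
  # uniformly lower left: everything reduced
  low <- nn; low$values[, 1] <- low$values[, 2] - 1
  expect_equal(paired_eye_shift(low, ids[1], ids[2])$frac_reduced, 1)
  expect_error(paired_eye_shift(nn, "nope", ids[1]), "unknown sample")
})
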