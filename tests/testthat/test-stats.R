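test_that("expectation_orders lists choose(L, k) copies of each order", {
  expect_identical(expectation_orders(2), c(0L, 1L, 1L, 2L))
  expect_identical(expectation_orders(3), c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L))
  expect_identical(expectation_orders(3, 5), c(0L, 1L, 1L, 1L, 2L))
  for (L in 1:6)
    expect_identical(tabulate(expectation_orders(L) + 1L, L + 1L),
                     as.integer(choose(L, 0:L)))
  expect_error(expectation_orders(3, 9), "in \\[1, 2\\^L\\]")
  expect_error(expectation_orders(0), ">= 1")
})

test_that("kendall_tau_b matches hand counts and endpoints", {
  expect_equal(kendall_tau_b(c(0, 1, 1, 2), c(0, 1, 1, 2)), 1)
  expect_equal(kendall_tau_b(c(0, 1, 2), c(2, 1, 0)), -1)
  expect_equal(kendall_tau_b(c(0, 1, 1, 2), c(0, 1, 2, 1)), 0.4)
  expect_error(kendall_tau_b(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
})

test_that("kendall_tau_b agrees with stats::cor on tied random vectors", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y),
                 stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("kendall_tau_b is symmetric and invariant to monotone relabeling", {
  set.seed(18)
  x <- sample(0:3, 20, replace = TRUE)
  y <- sample(0:3, 20, replace = TRUE)
  expect_equal(kendall_tau_b(x, y), kendall_tau_b(y, x))
  relab <- c(-5, 0, 7, 100)   # strictly increasing relabeling of 0:3
  expect_equal(kendall_tau_b(relab[x + 1], y), kendall_tau_b(x, y))
})

test_that("permutation test is one-tailed, seeded, and reproducible", {
  obs <- rev(expectation_orders(3))   # perfect anti-correlation
  pt <- permutation_test(obs, 3, n_reps = 2000, seed = 3)
  expect_lt(pt$tau_b, 0)
  expect_gt(pt$p_uncorrected, 0.5)
  pt2 <- permutation_test(obs, 3, n_reps = 2000, seed = 3)
  expect_identical(pt, pt2)
  expect_error(permutation_test(c(1, 1, 1), 3), "constant")
  expect_error(permutation_test(2L, 3), "at least 2")
})

test_that("zero exceedances print as a bound below 1/n_reps", {
  obs <- c(0L, rep(1L, 5), rep(2L, 10), rep(3L, 10), rep(4L, 5), 5L)
  pt <- permutation_test(obs, 5, n_reps = 500, seed = 5)
  expect_identical(pt$p_uncorrected, 0)
  expect_output(print(pt), "< 0.002")
})

test_that("holm_correct reproduces the textbook step-down adjustment", {
  expect_equal(holm_correct(0.01), 0.01)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_correct(c(0.5, 0.6, 0.9)), c(1, 1, 1))
  set.seed(19)
  p <- runif(10)
  expect_equal(holm_correct(p), brute_holm(p))
  expect_error(holm_correct(numeric(0)), "empty")
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("G statistic vanishes for uniform counts and matches hand values", {
  p <- (1:6 - 0.5) / 6   # one observation per equal-width bin
  g <- g_test_uniformity(p, bin_edges = seq(0, 1, by = 1 / 6))
  expect_equal(g$G, 0)
  expect_identical(g$df, 5L)
  g2 <- g_test_uniformity(c(0.2, 0.3), bin_edges = c(0, 0.5, 1))
  expect_equal(g2$G, 4 * log(2))
  expect_identical(g2$df, 1L)
})

test_that("G-test bins censored bounds and zeros into the lowest bin", {
  g <- g_test_uniformity(c(0, 1e-5, 0.5))
  expect_identical(g$observed[1], 2L)
  expect_error(g_test_uniformity(c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(g_test_uniformity(0.5, bin_edges = c(0, 1)), "at least 2")
  expect_error(g_test_uniformity(0.5, bin_edges = c(0.1, 0.5, 1)),
               "span")
})
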