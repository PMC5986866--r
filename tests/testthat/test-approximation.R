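test_that("rank_terms sorts by |E| with stable canonical tie-breaking", {
  rk <- rank_terms(walsh_spectrum(c(3, -1)))
  expect_identical(rk$ranked_indices, c(0L, 1L))
  expect_identical(rk$ranked_orders, c(0L, 1L))
  # all magnitudes tied: canonical ascending index order
  rk <- rank_terms(walsh_spectrum(c(0.25, -0.25, -0.25, 0.25)))
  expect_identical(rk$ranked_indices, 0:3)
  expect_identical(rk$ranked_orders, c(0L, 1L, 1L, 2L))
  # zeros trail in canonical order
  rk <- rank_terms(walsh_spectrum(c(0, 5, 0, 0)))
  expect_identical(rk$ranked_indices, c(1L, 0L, 2L, 3L))
})

test_that("rank_terms snaps round-off-scale magnitudes to exact ties", {
  E <- c(1, 0.5, 1e-17, -2e-17)   # transform noise, not signal
  rk <- rank_terms(walsh_spectrum(E))
  expect_identical(rk$ranked_indices, c(0L, 1L, 2L, 3L))
})

test_that("best_m_approximation reconstructs at the extremes", {
  set.seed(12)
  ls <- landscape(rnorm(16))
  sp <- walsh_forward(ls)
  expect_equal(best_m_approximation(sp, 16)$W, ls$W, tolerance = 1e-10)
  expect_equal(best_m_approximation(sp, 0)$W, rep(0, 16))
  expect_error(best_m_approximation(sp, 17), "m must be")
})

test_that("residual sequence follows Parseval bookkeeping", {
  # L = 1: m = 1 keeps only the mean term, which explains no variance
  seq1 <- residual_sequence(landscape(c(2, 4)))
  expect_equal(seq1$resid_fraction, c(1, 1, 0))
  # additive L = 3: zero residual at m = 4 (mean + three main effects)
  add <- walsh_inverse(c(1, 0.3, -0.2, 0, 0.1, 0, 0, 0))
  seqa <- residual_sequence(add)
  expect_equal(seqa$resid_fraction[5], 0, tolerance = 1e-12)
  expect_gt(seqa$resid_fraction[4], 0)
  # monotone from 1 to 0
  set.seed(13)
  sq <- residual_sequence(landscape(rnorm(32)))
  expect_equal(sq$resid_fraction[1], 1)
  expect_true(all(diff(sq$resid_fraction) <= 1e-12))
  expect_equal(sq$resid_fraction[33], 0)
  expect_error(residual_sequence(landscape(rep(2, 8))), "constant")
})

test_that("residual fractions equal directly recomputed residual variance", {
  # once the mean term is in the model (it ranks first when it dominates,
  # as on fitness-proxy scales), the fraction of variance about the mean
  # equals the reconstruction error of the best-m model
  set.seed(14)
  W <- rnorm(8) + 5
  ls <- landscape(W)
  sp <- walsh_forward(ls)
  sq <- residual_sequence(ls)
  denom <- sum((W - mean(W))^2)
  for (m in 1:8) {    # the mean term ranks first here, so m >= 1 holds it
    Wm <- best_m_approximation(sp, m)$W
    expect_equal(sq$resid_fraction[m + 1], sum((W - Wm)^2) / denom,
                 tolerance = 1e-10)
  }
  # for arbitrary landscapes the identity is on the excluded non-zeroth
  # coefficients, computed here from the matrix-transform oracle
  W2 <- rnorm(8)
  sq2 <- residual_sequence(landscape(W2))
  E2 <- matrix_walsh_forward(W2)
  tot <- sum(E2[-1]^2)
  for (m in 0:8) {
    kept <- sq2$ranked_indices[seq_len(m)]
    excl <- setdiff(setdiff(sq2$ranked_indices, kept), 0L)
    expect_equal(sq2$resid_fraction[m + 1], sum(E2[excl + 1]^2) / tot,
                 tolerance = 1e-10)
  }
})

test_that("truncation stops where remaining variance drops below threshold", {
  sq <- structure(list(resid_fraction = c(1, 0.4, 0.1, 0, 0), L = 2),
                  class = "approx_sequence")
  expect_identical(truncate_by_experimental_variance(sq, 0.15), 2L)
  expect_identical(truncate_by_experimental_variance(sq, 0), 3L)
  expect_warning(m0 <- truncate_by_experimental_variance(sq, 1.5),
                 "exceeds")
  expect_identical(m0, 0L)
})

test_that("per-order summary attributes squared-coefficient reductions", {
  sp <- walsh_spectrum(c(0.5, 0.4, 0.2, 0.1))
  sq <- residual_sequence(walsh_inverse(sp))
  tab <- per_order_summary(sq, sp)
  denom <- 0.4^2 + 0.2^2 + 0.1^2
  expect_equal(tab$aggregate_reduction[tab$order == 1],
               (0.4^2 + 0.2^2) / denom)
  expect_equal(tab$aggregate_reduction[tab$order == 2], 0.1^2 / denom)
  expect_identical(tab$n_terms[tab$order == 1], 2L)
  # reductions over all orders sum to 1 (order 0 contributes none)
  expect_equal(sum(tab$aggregate_reduction), 1)
  # additive landscape: everything at order 1
  add <- walsh_inverse(c(1, 0.3, -0.2, 0, 0.1, 0, 0, 0))
  sqa <- residual_sequence(add)
  taba <- per_order_summary(sqa)
  expect_equal(taba$aggregate_reduction[taba$order == 1], 1,
               tolerance = 1e-12)
})

test_that("serialized approximation sequences round-trip as tables", {
  set.seed(15)
  sq <- residual_sequence(landscape(rnorm(8)))
  f <- tempfile(fileext = ".tsv")
  write_approx_sequence(sq, f)
  back <- utils::read.delim(f, colClasses = c(subset = "character"))
  expect_equal(nrow(back), 8)
  expect_equal(back$resid_fraction, sq$resid_fraction[-1], tolerance = 1e-6)
  expect_identical(canonical_index(back$subset), sq$ranked_indices)
})
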