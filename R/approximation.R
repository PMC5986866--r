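# default snap tolerance: coefficients smaller than the accumulated
# round-off of the transform are numerically zero and must tie exactly,
# or the canonical tie order (and with it the determinism of downstream
# rank statistics on additive landscapes) is destroyed by noise at 1e-17.
default_zero_tol <- function(E) {
  8 * 2^round(log2(length(E))) * .Machine$double.eps * max(abs(E))
}

#' Rank epistatic terms by absolute magnitude
#'
#' Terms are sorted by descending `|E|`; ties (including all terms whose
#' magnitude is below `zero_tol`, which are snapped to zero first) are
#' broken by ascending canonical subset index, so the ranking is stable and
#' deterministic.
#'
#' @param sp a `walsh_spectrum`.
#' @param zero_tol magnitudes at or below this are treated as exactly zero
#'   before ranking. Default: `8 * 2^L * eps * max(|E|)`, the scale of
#'   accumulated transform round-off.
#' @return list with `ranked_indices` (0-based subset indices, a permutation
#'   of `0:(2^L-1)`) and `ranked_orders` (their popcounts).
#' @export
rank_terms <- function(sp, zero_tol = default_zero_tol(sp$E)) {
  stopifnot(inherits(sp, "walsh_spectrum"))
  a <- abs(sp$E)
  a[a <= zero_tol] <- 0
  ord <- order(-a, seq_along(a))
  list(ranked_indices = ord - 1L, ranked_orders = sp$orders[ord])
}

#' Best m-term subsetting approximation
#'
#' Reconstructs the landscape from the `m` largest-magnitude epistatic
#' terms, the remaining `2^L - m` set to zero. By the orthogonality of the
#' Walsh transform this attains the minimum sum-of-squares distance to the
#' original landscape over all m-term subsets.
#'
#' @param sp a `walsh_spectrum`.
#' @param m number of terms retained, `0 <= m <= 2^L`.
#' @param zero_tol tie tolerance passed to [rank_terms()].
#' @return a [landscape].
#' @export
best_m_approximation <- function(sp, m, zero_tol = default_zero_tol(sp$E)) {
  stopifnot(inherits(sp, "walsh_spectrum"))
  n <- length(sp$E)
  if (m < 0 || m > n) stop("m must be in [0, 2^L]")
  keep <- rank_terms(sp, zero_tol)$ranked_indices[seq_len(m)] + 1L
  Em <- numeric(n)
  Em[keep] <- sp$E[keep]
  walsh_inverse(Em)
}

#' Residual-variance sequence of the best-m approximations
#'
#' For every `m` in `0..2^L`, the residual variance of the best-m model as
#' a fraction of the landscape's total variance about its mean. By
#' Parseval's identity the residual fraction is the sum of squared
#' *excluded* non-zeroth coefficients over the sum over all non-zeroth
#' coefficients, so the sequence starts at 1, is non-increasing, and ends
#' at 0; the order-0 (mean) term explains none of the variance about the
#' mean.
#'
#' When `exp_var_fraction` is supplied, the sequence is truncated where the
#' remaining model variance first drops below the experimental variance
#' (see [truncate_by_experimental_variance()]); otherwise `m_star = 2^L`.
#'
#' @param ls a [landscape] with nonconstant `W`.
#' @param exp_var_fraction optional truncation threshold (experimental
#'   variance as a fraction of model variance).
#' @param zero_tol tie tolerance passed to [rank_terms()].
#' @return object of class `approx_sequence`: list with `L`,
#'   `ranked_indices`, `ranked_orders`, `resid_fraction` (length `2^L + 1`,
#'   entry `m + 1` is the best-m residual fraction), `m_star`,
#'   `exp_var_fraction`, and the `spectrum`.
#' @export
residual_sequence <- function(ls, exp_var_fraction = NULL,
                              zero_tol = NULL) {
  stopifnot(inherits(ls, "landscape"))
  sp <- walsh_forward(ls)
  if (is.null(zero_tol)) zero_tol <- default_zero_tol(sp$E)
  rk <- rank_terms(sp, zero_tol)
  denom <- sum(sp$E[-1L]^2)
  if (denom == 0) stop("constant landscape: residual fractions undefined")
  contrib <- sp$E[rk$ranked_indices + 1L]^2
  contrib[rk$ranked_indices == 0L] <- 0
  resid <- c(1, 1 - cumsum(contrib) / denom)
  resid[length(resid)] <- 0     # exact by construction; kill round-off
  seq <- structure(list(L = sp$L,
                        ranked_indices = rk$ranked_indices,
                        ranked_orders = rk$ranked_orders,
                        resid_fraction = resid,
                        m_star = length(sp$E),
                        exp_var_fraction = exp_var_fraction,
                        spectrum = sp),
                   class = "approx_sequence")
  if (!is.null(exp_var_fraction))
    seq$m_star <- truncate_by_experimental_variance(seq, exp_var_fraction)
  seq
}

#' @export
print.approx_sequence <- function(x, ...) {
  n <- 2^x$L
  cat("Best-m approximation sequence: L =", x$L, "\n")
  cat("  m_star =", x$m_star, "of", n, "terms retained",
      if (!is.null(x$exp_var_fraction))
        paste0("(experimental variance fraction ",
               format(x$exp_var_fraction, digits = 4), ")"), "\n")
  cat("  first ranked orders:",
      paste(utils::head(x$ranked_orders, 10L), collapse = " "), "...\n")
  invisible(x)
}

#' Truncation point set by experimental variance
#'
#' Returns the smallest `m` whose remaining (residual) model-variance
#' fraction is below `exp_var_fraction`; the `j = 2^L - m_star` trailing
#' terms are then dropped from downstream order statistics. A threshold of
#' exactly 0 truncates where the residual first reaches 0. Thresholds at or
#' above the full variance give `m_star = 0` with a warning.
#'
#' @param seq an `approx_sequence`.
#' @param exp_var_fraction nonnegative threshold.
#' @return integer `m_star`.
#' @export
truncate_by_experimental_variance <- function(seq, exp_var_fraction) {
  stopifnot(inherits(seq, "approx_sequence"))
  if (exp_var_fraction < 0) stop("exp_var_fraction must be >= 0")
  resid <- seq$resid_fraction
  hit <- if (exp_var_fraction == 0) which(resid <= 1e-12)
         else which(resid < exp_var_fraction)
  m_star <- if (length(hit)) hit[1L] - 1L else length(resid) - 1L
  if (m_star == 0L)
    warning("experimental variance exceeds total model variance; ",
            "no terms retained")
  m_star
}

#' Per-order summary of explained variance
#'
#' Attributes to each retained term its reduction in residual-variance
#' fraction, `E[k]^2 / sum(E[j != 0]^2)` (zero for the order-0 term), and
#' aggregates over epistatic orders: total reduction, number of retained
#' terms, and mean reduction per term. Orders with no retained terms are
#' omitted.
#'
#' @param seq an `approx_sequence`.
#' @param sp the matching `walsh_spectrum` (defaults to the one stored in
#'   `seq`).
#' @return data.frame with columns `order`, `aggregate_reduction`,
#'   `n_terms`, `mean_reduction`.
#' @export
per_order_summary <- function(seq, sp = seq$spectrum) {
  stopifnot(inherits(seq, "approx_sequence"), inherits(sp, "walsh_spectrum"))
  denom <- sum(sp$E[-1L]^2)
  idx <- seq$ranked_indices[seq_len(seq$m_star)]
  red <- sp$E[idx + 1L]^2 / denom
  red[idx == 0L] <- 0
  ord <- sp$orders[idx + 1L]
  orders <- sort(unique(ord))
  data.frame(order = orders,
             aggregate_reduction = vapply(orders, function(o)
               sum(red[ord == o]), numeric(1)),
             n_terms = vapply(orders, function(o)
               sum(ord == o), integer(1)),
             mean_reduction = vapply(orders, function(o)
               mean(red[ord == o]), numeric(1)))
}

#' Write an approximation sequence as delimited text
#'
#' One row per `m >= 1`: `m`, the added term's subset bitstring, its order
#' and magnitude, and the best-m residual-variance fraction.
#'
#' @param seq an `approx_sequence`.
#' @param path output path; `.csv` comma-separated, else tab.
#' @export
write_approx_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "approx_sequence"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(
    m = seq_along(seq$ranked_indices),
    subset = genotype_strings(seq$L)[seq$ranked_indices + 1L],
    order = seq$ranked_orders,
    abs_coefficient = abs(seq$spectrum$E[seq$ranked_indices + 1L]),
    resid_fraction = seq$resid_fraction[-1L])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
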