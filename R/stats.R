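#' Combinatoric expectation of epistatic orders
#'
#' If the influence of epistatic terms declines with order, the orders of
#' the magnitude-ranked coefficients should read: one 0, then `L` ones,
#' `choose(L, 2)` twos, and in general `choose(L, k)` values `k` -- the
#' sorted multiset of popcounts. When `n` is given (a truncated study), the
#' first `n` entries are returned, i.e. the last `2^L - n` values are
#' dropped.
#'
#' @param L number of loci.
#' @param n optional truncated length, `0 < n <= 2^L`.
#' @return integer vector of expected orders.
#' @examples
#' expectation_orders(3)      # 0 1 1 1 2 2 2 3
#' expectation_orders(3, 5)   # 0 1 1 1 2
#' @export
expectation_orders <- function(L, n = NULL) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  eo <- rep(0:L, choose(L, 0:L))
  if (is.null(n)) return(eo)
  if (n < 1 || n > length(eo)) stop("n must be in [1, 2^L]")
  eo[seq_len(n)]
}

# tau-b numerator and tie-corrected denominator from a contingency table;
# O(c^2) given the table, which keeps the permutation loop cheap
tau_b_from_table <- function(tab) {
  r <- nrow(tab); c <- ncol(tab)
  Ur <- matrix(0, r, r); Ur[upper.tri(Ur)] <- 1   # Ur[i, i'] = 1 iff i' > i
  Uc <- matrix(0, c, c); Uc[upper.tri(Uc)] <- 1
  conc <- sum(tab * (Ur %*% tab %*% t(Uc)))
  disc <- sum(tab * (Ur %*% tab %*% Uc))
  n <- sum(tab)
  n0 <- n * (n - 1) / 2
  n1 <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  n2 <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  if (n0 == n1 || n0 == n2)
    stop("constant vector: tau-b undefined (denominator zero)")
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation,
#' `tau_b = (P - Q) / sqrt((P + Q + Tx) (P + Q + Ty))` with `P` concordant
#' pairs, `Q` discordant, and `Tx`/`Ty` pairs tied in one variable only.
#' Computed from the joint contingency table in `O(n log n + c^2)` for `c`
#' distinct values, which makes dense permutation nulls over small ordinal
#' supports (epistatic orders) cheap.
#'
#' @param x,y equal-length vectors, neither constant.
#' @return tau-b in `[-1, 1]`.
#' @examples
#' kendall_tau_b(c(0, 1, 1, 2), c(0, 1, 2, 1))  # 0.4
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  xf <- match(x, sort(unique(x)))
  yf <- match(y, sort(unique(y)))
  r <- max(xf); c <- max(yf)
  tab <- matrix(tabulate((xf - 1L) * c + yf, r * c), r, c, byrow = TRUE)
  tau_b_from_table(tab)
}

#' Permutation test for declining epistatic influence
#'
#' Computes the empirical tau-b between an observed (possibly truncated)
#' sequence of magnitude-ranked epistatic orders and the combinatoric
#' expectation [expectation_orders()], then compares it against a null
#' distribution of tau-b values between two independent uniformly random
#' permutations of that same expectation multiset. The one-tailed P value
#' is the fraction of null draws greater than or equal to the empirical
#' value; when no draw qualifies, `p_uncorrected` is 0 and the print method
#' reports `< 1/n_reps`.
#'
#' @param observed_orders integer vector: orders of the ranked terms,
#'   truncated to the retained prefix.
#' @param L number of loci.
#' @param n_reps number of null permutation pairs.
#' @param seed RNG seed (set with [set.seed()]; recorded in the result).
#' @return list of class `perm_test` with `tau_b`, `p_uncorrected`,
#'   `n_terms`, `n_reps`, `seed`.
#' @export
permutation_test <- function(observed_orders, L, n_reps = 1e5, seed = 1) {
  n_terms <- length(observed_orders)
  if (n_terms < 2L) stop("need at least 2 observed orders")
  if (length(unique(observed_orders)) < 2L)
    stop("constant observed orders: tau-b undefined")
  eo <- expectation_orders(L, n_terms)
  tau_emp <- kendall_tau_b(observed_orders, eo)

  # null: both sides permute the expectation multiset; its marginals (and
  # hence the tau-b denominator) are fixed, so only the numerator varies
  set.seed(seed)
  K <- L + 1L
  Ur <- matrix(0, K, K); Ur[upper.tri(Ur)] <- 1
  tUr <- t(Ur)
  cnt <- tabulate(eo + 1L, K)
  n0 <- n_terms * (n_terms - 1) / 2
  nt <- sum(cnt * (cnt - 1) / 2)
  den <- n0 - nt                      # same tie structure on both sides
  if (den <= 0) stop("expectation multiset is constant at this truncation")
  null_tau <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    xp <- sample(eo)
    yp <- sample(eo)
    tab <- matrix(tabulate(xp * K + yp + 1L, K * K), K, K, byrow = TRUE)
    null_tau[i] <- (sum(tab * (Ur %*% tab %*% tUr)) -
                    sum(tab * (Ur %*% tab %*% Ur))) / den
  }
  structure(list(tau_b = tau_emp,
                 p_uncorrected = mean(null_tau >= tau_emp),
                 n_terms = n_terms, n_reps = n_reps, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  p <- if (x$p_uncorrected == 0) paste0("< ", format(1 / x$n_reps))
       else format(x$p_uncorrected)
  cat("Permutation test of declining epistatic influence\n")
  cat("  tau_b =", format(x$tau_b, digits = 4), "over", x$n_terms,
      "terms; one-tailed P =", p,
      paste0("(", format(x$n_reps, scientific = FALSE), " permutation pairs, seed ",
             x$seed, ")\n"))
  invisible(x)
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment of a vector of P values (monotone, capped at
#' 1). Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted P values in input order.
#' @export
holm_correct <- function(p_values) {
  if (length(p_values) == 0L) stop("empty P-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("P values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' G-test of P-value uniformity across studies
#'
#' Bins a set of uncorrected P values (default: six log-decade bins with
#' edges at `10^-5 ... 10^-1` on `(0, 1]`, the lowest bin closed at 0 so
#' that censored "less than" bounds and exact zeros fall there) and tests
#' the observed counts against the uniform expectation with the
#' likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` over non-empty
#' bins, referred to the chi-squared distribution with `bins - 1` degrees
#' of freedom.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param bin_edges increasing vector of edges spanning `[0, 1]`.
#' @return list of class `g_test` with `G`, `df`, `p_value`, `observed`,
#'   `expected`, `bin_edges`.
#' @export
g_test_uniformity <- function(p_values,
                              bin_edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2,
                                            1e-1, 1)) {
  if (length(bin_edges) < 3L) stop("need at least 2 bins")
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must increase")
  if (bin_edges[1L] != 0 || bin_edges[length(bin_edges)] != 1)
    stop("bin edges must span [0, 1]")
  if (any(p_values < 0 | p_values > 1)) stop("P values must lie in [0, 1]")
  bin <- findInterval(p_values, bin_edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  bin[bin == 0L] <- 1L                 # p = 0 (censored bounds) -> lowest bin
  nb <- length(bin_edges) - 1L
  O <- tabulate(bin, nb)
  E <- length(p_values) * diff(bin_edges)
  nz <- O > 0
  G <- 2 * sum(O[nz] * log(O[nz] / E[nz]))
  df <- nb - 1L
  structure(list(G = G, df = df,
                 p_value = stats::pchisq(G, df, lower.tail = FALSE),
                 observed = O, expected = E, bin_edges = bin_edges),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat("G-test of P-value uniformity: G =", format(x$G, digits = 6),
      ", df =", x$df, ", P =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
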