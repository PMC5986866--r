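#' Draw a Walsh spectrum with controlled per-order scales
#'
#' Generates epistatic terms `E[k] ~ N(0, order_scale[popcount(k) + 1]^2)`
#' independently, with the order-0 term fixed at `e0`. Geometric decay of
#' `order_scale` emulates landscapes whose epistatic influence declines
#' with interaction order; a constant `order_scale` gives i.i.d.
#' coefficients, the signature of i.i.d. genotype fitness values (the
#' maximally rugged limit).
#'
#' @param L number of loci.
#' @param order_scale numeric vector of `L + 1` nonnegative standard
#'   deviations, one per order `0..L` (entry 1 is unused beyond validation;
#'   the order-0 term is fixed).
#' @param e0 fixed order-0 (mean fitness) term; the default 1 keeps the
#'   mean term top-ranked, as in empirical landscapes. `NULL` draws it like
#'   every other term, with `order_scale[1]` -- required for a spectrum
#'   whose coefficients are genuinely all i.i.d. (a pinned mean term always
#'   ranks first and biases rank statistics away from zero).
#' @param seed RNG seed.
#' @return a `walsh_spectrum`.
#' @export
decaying_spectrum <- function(L, order_scale, e0 = 1, seed = 1) {
  L <- as.integer(L)
  if (length(order_scale) != L + 1L)
    stop("order_scale must have length L + 1")
  if (any(order_scale < 0)) stop("order_scale entries must be >= 0")
  set.seed(seed)
  orders <- epistatic_order(0:(2^L - 1L))
  E <- stats::rnorm(2^L, mean = 0, sd = order_scale[orders + 1L])
  if (!is.null(e0)) E[1L] <- e0
  walsh_spectrum(E)
}

#' Build a noisy landscape from a known spectrum
#'
#' Inverse-transforms a coefficient vector to its landscape and emulates a
#' measurement experiment: each genotype's reported fitness is the mean of
#' `n_reps` draws from `N(W_g, noise_sd^2)` and its reported variance is
#' the sample variance of those draws. With `noise_sd = 0` the exact
#' landscape is returned (variance 0 when replicates were requested);
#' with `n_reps = 1` no variance column is produced.
#'
#' @param E numeric vector of `2^L` epistatic terms, or a `walsh_spectrum`.
#' @param noise_sd per-measurement Gaussian noise standard deviation.
#' @param n_reps replicates per genotype.
#' @param seed RNG seed (unused when `noise_sd = 0`).
#' @return a [landscape] whose `nrep` records the replicate count.
#' @export
landscape_from_spectrum <- function(E, noise_sd = 0, n_reps = 1, seed = 1) {
  if (inherits(E, "walsh_spectrum")) E <- E$E
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ls <- walsh_inverse(E)
  n <- length(ls$W)
  if (noise_sd == 0) {
    var <- if (n_reps > 1L) numeric(n)
    return(landscape(ls$W, var = var,
                     nrep = if (n_reps > 1L) rep(n_reps, n),
                     meta = "synthetic, noiseless"))
  }
  set.seed(seed)
  draws <- matrix(stats::rnorm(n * n_reps, mean = rep(ls$W, each = n_reps),
                               sd = noise_sd), nrow = n_reps)
  W <- colMeans(draws)
  var <- if (n_reps > 1L) apply(draws, 2L, stats::var)
  landscape(W, var = var, nrep = if (n_reps > 1L) rep(n_reps, n),
            meta = sprintf("synthetic, noise_sd=%g n_reps=%d seed=%d",
                           noise_sd, n_reps, seed))
}
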