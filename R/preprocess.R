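#' Taylor approximation of log-scale moments
#'
#' When only a mean and an experimental variance are reported for a
#' genotype (not individual replicates), the mean and variance of the
#' log-transformed measurement are approximated by second-order Taylor
#' expansion: `log_mean = ln(mean) - var / (2 * mean^2)` and
#' `log_var = var / mean^2`.
#'
#' @param mean positive numeric vector of reported means.
#' @param var nonnegative numeric vector of reported variances.
#' @return list with numeric vectors `log_mean` and `log_var`.
#' @examples
#' approx_log_moments(10, 4)   # log_mean = ln(10) - 0.02, log_var = 0.04
#' @export
approx_log_moments <- function(mean, var) {
  if (any(mean <= 0)) stop("mean must be > 0 for log-scale moments")
  if (any(var < 0)) stop("var must be >= 0")
  list(log_mean = log(mean) - var / (2 * mean^2),
       log_var = var / mean^2)
}

#' Convert a 95% confidence interval to a variance
#'
#' Applies `s^2 = (n * ci95 / 1.96)^2` under the assumption of normally
#' distributed noise.
#'
#' Note: the conventional back-calculation from a CI half-width to a sample
#' variance would use `sqrt(n)` rather than `n`; the formula here is applied
#' literally as stated, with the `n` multiplier, so that analyses using it
#' are reproducible as specified. Override upstream if your source reports a
#' conventional interval.
#'
#' @param ci95 positive half-width of the 95% confidence interval.
#' @param n positive replicate count.
#' @return numeric variance.
#' @examples
#' ci95_to_variance(1.96, 1)  # 1
#' @export
ci95_to_variance <- function(ci95, n) {
  if (any(ci95 <= 0)) stop("ci95 must be > 0")
  if (any(n < 1)) stop("n must be >= 1")
  (n * ci95 / 1.96)^2
}

#' Log-transform a landscape's fitness scale
#'
#' Growth-rate and drug-resistance proxies are usually analysed on a
#' natural-log scale. Positive fitness values are replaced by their log;
#' exact zeros are replaced by `zero_fill` (default -2, roughly one log
#' order below typical smallest nonzero log values). When per-genotype
#' variances are present, means and variances are propagated with the
#' Taylor rules of [approx_log_moments()]; zero-fitness genotypes get
#' log-scale variance 0 (no information survives the fill).
#'
#' @param ls a [landscape] with nonnegative fitness values.
#' @param zero_fill value substituted for `log(0)`.
#' @return a [landscape] on the log scale.
#' @export
log_transform_landscape <- function(ls, zero_fill = -2) {
  stopifnot(inherits(ls, "landscape"))
  if (any(ls$W < 0)) stop("negative fitness values cannot be log-transformed")
  zero <- ls$W == 0
  W <- numeric(length(ls$W))
  var <- NULL
  if (is.null(ls$var)) {
    W[!zero] <- log(ls$W[!zero])
  } else {
    m <- approx_log_moments(ls$W[!zero], ls$var[!zero])
    W[!zero] <- m$log_mean
    var <- numeric(length(ls$W))
    var[!zero] <- m$log_var
  }
  W[zero] <- zero_fill
  landscape(W, var = var, nrep = ls$nrep, labels = ls$labels,
            meta = paste0(if (is.null(ls$meta)) "" else paste0(ls$meta, "; "),
                          "natural-log scale (zero_fill ", zero_fill, ")"))
}

#' Pooled experimental variance as a fraction of model variance
#'
#' Pools per-genotype experimental variances by unweighted mean and divides
#' by the total model variance, the population (divide by `2^L`) mean
#' squared deviation of `W` about its mean. The population convention
#' matches the Parseval bookkeeping of the Walsh decomposition, where the
#' variance about the mean equals the sum of squared non-zeroth epistatic
#' terms.
#'
#' @param ls a [landscape] with `var` present.
#' @return list of class `variance_summary` with `pooled_var`, `model_var`,
#'   `exp_var_fraction`.
#' @export
experimental_variance_fraction <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  if (is.null(ls$var)) stop("landscape has no experimental variances")
  model_var <- mean((ls$W - mean(ls$W))^2)
  if (model_var == 0)
    stop("constant landscape: experimental variance fraction undefined")
  pooled <- mean(ls$var)
  structure(list(pooled_var = pooled, model_var = model_var,
                 exp_var_fraction = pooled / model_var),
            class = "variance_summary")
}
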