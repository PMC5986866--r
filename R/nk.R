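#' Simulate a Kauffman NK fitness landscape
#'
#' Each of `N` loci contributes a fitness component that depends on its own
#' allelic state and the states of `K` other loci drawn uniformly at random
#' without replacement. Contribution values are i.i.d. uniform on `[0, 1)`
#' and genotype fitness is the mean of the `N` contributions, the standard
#' Kauffman formulation; `K` tunes the amount of epistasis from purely
#' additive (`K = 0`) to i.i.d. fitness values (`K = N - 1`).
#'
#' Contribution tables are indexed by the focal locus state in the lowest
#' bit and the neighbour states (in stored neighbourhood order) in ascending
#' higher bits.
#'
#' @param N number of loci (`>= 1`).
#' @param K number of epistatic neighbours per locus, in `[0, N - 1]`.
#' @param seed RNG seed; the same `(N, K, seed)` always reproduces the same
#'   landscape.
#' @return list with elements `landscape` (a [landscape] of `2^N` fitness
#'   values, no experimental variances) and `config` (class `nk_config`:
#'   `N`, `K`, `seed`, `neighborhoods`, `tables`).
#' @examples
#' sim <- generate_nk(4, 1, seed = 7)
#' count_maxima(sim$landscape)
#' @export
generate_nk <- function(N, K, seed = 1) {
  N <- as.integer(N); K <- as.integer(K)
  if (N < 1L) stop("N must be >= 1")
  if (K < 0L || K > N - 1L) stop("K must be in [0, N - 1]")
  set.seed(seed)
  neighborhoods <- lapply(seq_len(N), function(i)
    if (K == 0L) integer(0) else sort(sample(setdiff(seq_len(N), i), K)))
  tables <- lapply(seq_len(N), function(i) stats::runif(2^(K + 1L)))
  g <- 0:(2^N - 1L)
  bits <- vapply(0:(N - 1L),
                 function(b) bitwAnd(bitwShiftR(g, b), 1L), integer(length(g)))
  W <- rowMeans(vapply(seq_len(N), function(i) {
    idx <- bits[, i]
    if (K > 0L)
      idx <- idx + as.integer(bits[, neighborhoods[[i]], drop = FALSE] %*%
                                2^(1:K))
    tables[[i]][idx + 1L]
  }, numeric(length(g))))
  cfg <- structure(list(N = N, K = K, seed = seed,
                        neighborhoods = neighborhoods, tables = tables),
                   class = "nk_config")
  list(landscape = landscape(W, meta = sprintf("NK simulation N=%d K=%d seed=%d",
                                               N, K, seed)),
       config = cfg)
}

#' Serialize an NK configuration to JSON
#'
#' Stores `N`, `K`, `seed`, neighbourhoods, and contribution tables with
#' full precision so a simulated landscape is exactly reproducible.
#'
#' @param cfg an `nk_config`.
#' @param path output path.
#' @export
write_nk_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "nk_config"))
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an NK configuration from JSON and rebuild its landscape
#'
#' @param path path written by [write_nk_config()].
#' @return list with `landscape` and `config`, as from [generate_nk()].
#' @export
read_nk_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # equal-length elements may come back simplified into a matrix
  as_rows <- function(x, f) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) f(x[i, ]))
    else lapply(x, f)
  }
  cfg <- structure(list(N = as.integer(raw$N), K = as.integer(raw$K),
                        seed = as.integer(raw$seed),
                        neighborhoods = as_rows(raw$neighborhoods, as.integer),
                        tables = as_rows(raw$tables, as.numeric)),
                   class = "nk_config")
  N <- cfg$N; K <- cfg$K
  g <- 0:(2^N - 1L)
  bits <- vapply(0:(N - 1L),
                 function(b) bitwAnd(bitwShiftR(g, b), 1L), integer(length(g)))
  W <- rowMeans(vapply(seq_len(N), function(i) {
    idx <- bits[, i]
    if (K > 0L)
      idx <- idx + as.integer(bits[, cfg$neighborhoods[[i]], drop = FALSE] %*%
                                2^(1:K))
    cfg$tables[[i]][idx + 1L]
  }, numeric(length(g))))
  list(landscape = landscape(W, meta = sprintf("NK from %s", path)),
       config = cfg)
}

#' Count local fitness maxima
#'
#' A genotype is a local maximum when its fitness is strictly greater than
#' that of all `L` Hamming-distance-1 neighbours. Genotypes tied with their
#' best neighbour are not counted and trigger a warning, since silent
#' double-counting of plateaus would corrupt topography summaries.
#'
#' @param ls a [landscape].
#' @return integer number of maxima.
#' @export
count_maxima <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  g <- 0:(2^ls$L - 1L)
  nb_max <- rep(-Inf, length(g))
  for (b in 0:(ls$L - 1L))
    nb_max <- pmax(nb_max, ls$W[bitwXor(g, bitwShiftL(1L, b)) + 1L])
  ties <- ls$W == nb_max
  if (any(ties))
    warning(sum(ties), " genotype(s) tied with their best neighbour; ",
            "not counted as maxima")
  sum(ls$W > nb_max)
}
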