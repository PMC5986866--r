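#' Sylvester-ordered Hadamard matrix
#'
#' Returns the symmetric `2^L x 2^L` matrix with entry
#' `(j, k) = (-1)^popcount(j AND k)` (rows and columns indexed from 0).
#' Rows are mutually orthogonal, so `Psi %*% Psi = 2^L * I`.
#'
#' @param L number of loci (`L = 0` gives the 1x1 matrix `[1]`).
#' @return integer matrix of +1/-1 entries.
#' @examples
#' hadamard_matrix(1)  # rbind(c(1, 1), c(1, -1))
#' @export
hadamard_matrix <- function(L) {
  L <- as.integer(L)
  if (L < 0L) stop("L must be >= 0")
  H <- matrix(1L, 1L, 1L)
  for (i in seq_len(L)) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' Epistatic order of a subset index
#'
#' The order of interaction term `k` is the number of set bits of `k`
#' (order 0 = global mean, order 1 = main effects, ...).
#'
#' @param k integer vector of subset indices.
#' @param L optional number of loci; when given, indices are range-checked
#'   against `[0, 2^L)`.
#' @return integer vector of popcounts.
#' @export
epistatic_order <- function(k, L = NULL) {
  k <- as.integer(k)
  if (any(k < 0L)) stop("subset index must be >= 0")
  if (!is.null(L) && any(k >= 2^L)) stop("subset index out of range for L = ", L)
  vapply(k, function(z) {
    n <- 0L
    while (z > 0L) { n <- n + bitwAnd(z, 1L); z <- bitwShiftR(z, 1L) }
    n
  }, integer(1))
}

# in-place fast Walsh-Hadamard butterfly, O(n log n); bit-identical with the
# explicit Psi %*% x product up to the usual reordering of exact additions
fwht <- function(x) {
  n <- length(x)
  h <- 1L
  while (h < n) {
    for (start in seq.int(1L, n, by = 2L * h)) {
      i <- start:(start + h - 1L)
      a <- x[i]; b <- x[i + h]
      x[i] <- a + b
      x[i + h] <- a - b
    }
    h <- 2L * h
  }
  x
}

#' Forward Fourier-Walsh transform of a landscape
#'
#' Computes the full vector of `2^L` epistatic terms
#' `E = Psi %*% W / 2^L` in canonical subset order: the set bits of index
#' `k` name the interacting loci, and `popcount(k)` is the term's epistatic
#' order. `E[0]` is the arithmetic mean of `W`; signs of individual terms
#' depend on the (documented, fixed) allele-coding convention, while
#' magnitudes and orders do not.
#'
#' @param ls a [landscape].
#' @return object of class `walsh_spectrum`: list with `L`, `E` (numeric,
#'   length `2^L`), and `orders` (`popcount(k)` for each index).
#' @examples
#' walsh_forward(landscape(c(2, 4)))  # E = c(3, -1)
#' @export
walsh_forward <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  E <- fwht(ls$W) / 2^ls$L
  structure(list(L = ls$L, E = E,
                 orders = epistatic_order(0:(2^ls$L - 1L))),
            class = "walsh_spectrum")
}

#' Inverse Fourier-Walsh transform
#'
#' Reconstructs the fitness landscape `W = Psi %*% E` from a vector of
#' epistatic terms; exact inverse of [walsh_forward()] up to round-off.
#'
#' @param sp a `walsh_spectrum`, or a bare numeric vector of length `2^L`.
#' @return a [landscape].
#' @export
walsh_inverse <- function(sp) {
  E <- if (inherits(sp, "walsh_spectrum")) sp$E else as.numeric(sp)
  n <- length(E)
  if (n < 1L || bitwAnd(n, n - 1L) != 0L)
    stop("length of E must be a power of two")
  landscape(fwht(E))
}

#' Construct a spectrum object from a coefficient vector
#'
#' @param E numeric vector of `2^L` epistatic terms in canonical subset order.
#' @return a `walsh_spectrum`.
#' @export
walsh_spectrum <- function(E) {
  E <- as.numeric(E)
  n <- length(E)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("length of E must be a power of two >= 2")
  L <- as.integer(round(log2(n)))
  structure(list(L = L, E = E, orders = epistatic_order(0:(n - 1L))),
            class = "walsh_spectrum")
}

#' @export
print.walsh_spectrum <- function(x, ...) {
  cat("Walsh spectrum: L =", x$L, "(", length(x$E), "terms )\n")
  ss <- fourier_spectrum(x)
  cat("  sum of squares by order:",
      paste(format(ss$per_order_ss, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Fourier spectrum: summed squared coefficients by order
#'
#' For each interaction order `o` in `0..L`, the sum of squared epistatic
#' terms of that order. When every genotype's fitness is i.i.d., the
#' expected spectrum is proportional to `choose(L, o)`.
#'
#' @param sp a `walsh_spectrum`.
#' @return list of class `fourier_spectrum` with `per_order_ss` (length
#'   `L + 1`) and `L`.
#' @export
fourier_spectrum <- function(sp) {
  stopifnot(inherits(sp, "walsh_spectrum"))
  ss <- vapply(0:sp$L, function(o) sum(sp$E[sp$orders == o]^2), numeric(1))
  structure(list(L = sp$L, per_order_ss = ss), class = "fourier_spectrum")
}

#' Write a spectrum as delimited text
#'
#' Columns: subset bitstring, order, coefficient.
#'
#' @param sp a `walsh_spectrum`.
#' @param path output path; `.csv` comma-separated, else tab.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "walsh_spectrum"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(subset = genotype_strings(sp$L), order = sp$orders,
                    coefficient = sp$E)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
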