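# Independent oracles kept deliberately naive: these re-derive the same
# quantities as the package by direct enumeration / explicit linear algebra
# and must never call the code paths they check.

# O(n^2) Kendall tau-b by explicit pair counting
brute_tau_b <- function(x, y) {
  n <- length(x)
  P <- Q <- Tx <- Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (dx * dy > 0) P <- P + 1
    else Q <- Q + 1
  }
  (P - Q) / sqrt((P + Q + Tx) * (P + Q + Ty))
}

# explicit-matrix Walsh transform (the stated oracle for the fast version)
matrix_walsh_forward <- function(W) {
  L <- round(log2(length(W)))
  as.vector(hadamard_matrix(L) %*% W) / 2^L
}

matrix_walsh_inverse <- function(E) {
  L <- round(log2(length(E)))
  as.vector(hadamard_matrix(L) %*% E)
}

# all distinct permutations of a (small) multiset, one per row
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  unique(out)
}

# textbook step-down Holm adjustment
brute_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, (n - seq_len(n) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(n)
  out[o] <- adj
  out
}

# write a landscape-format file from raw columns, for reader tests
write_raw_landscape <- function(path, genotype, fitness, variance = NULL,
                                n = NULL, sep = "\t") {
  df <- data.frame(genotype = genotype, fitness = fitness)
  if (!is.null(variance)) df$variance <- variance
  if (!is.null(n)) df$n <- n
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
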