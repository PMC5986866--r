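#' Combinatorially complete fitness landscapes
#'
#' A `landscape` holds one fitness value (or proxy: growth rate, MIC, IC50,
#' replicative capacity) for every one of the `2^L` genotypes defined by `L`
#' biallelic loci, in canonical order, plus optional per-genotype experimental
#' variances and replicate counts.
#'
#' Canonical order is ascending `L`-bit binary: genotype index `g` has a
#' mutation at locus `b` exactly when bit `b` of `g` is set. In genotype
#' *strings* the leftmost character is the highest-order bit (locus `L`
#' reads first); index 0, the all-zeros string, is the reference genotype.
#' All downstream statistics are invariant to this labelling convention, but
#' individual coefficient identities are not, so it is fixed here once.
#'
#' @param W numeric vector of `2^L` fitness values in canonical order.
#' @param var optional numeric vector of `2^L` nonnegative experimental
#'   variances (same scale as `W`).
#' @param nrep optional integer vector of `2^L` positive replicate counts.
#' @param labels optional character vector of `L` locus names.
#' @param meta free-text provenance, kept verbatim.
#' @return An object of class `landscape`: a list with elements `L`, `W`,
#'   `var`, `nrep`, `labels`, `meta`.
#' @examples
#' landscape(c(0, 1, 2, 3))        # L = 2, additive
#' @export
landscape <- function(W, var = NULL, nrep = NULL, labels = NULL, meta = NULL) {
  W <- as.numeric(W)
  n <- length(W)
  L <- as.integer(round(log2(n)))
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("length(W) must be a power of two >= 2, got ", n)
  if (anyNA(W)) stop("W must not contain NA")
  if (!is.null(var)) {
    var <- as.numeric(var)
    if (length(var) != n) stop("var must have length 2^L = ", n)
    if (anyNA(var) || any(var < 0)) stop("var entries must be nonnegative")
  }
  if (!is.null(nrep)) {
    nrep <- as.integer(nrep)
    if (length(nrep) != n) stop("nrep must have length 2^L = ", n)
    if (anyNA(nrep) || any(nrep < 1L)) stop("nrep entries must be positive")
  }
  if (!is.null(labels) && length(labels) != L)
    stop("labels must have length L = ", L)
  structure(list(L = L, W = W, var = var, nrep = nrep,
                 labels = labels, meta = meta),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("Combinatorially complete landscape: L =", x$L,
      "loci,", length(x$W), "genotypes\n")
  cat("  fitness range [", format(min(x$W)), ",", format(max(x$W)), "]",
      if (!is.null(x$var)) "; experimental variances present" else "", "\n",
      sep = "")
  if (!is.null(x$meta)) cat("  meta:", x$meta, "\n")
  invisible(x)
}

#' Canonical genotype index of a bitstring
#'
#' Maps an `L`-character 0/1 genotype string to its canonical integer index.
#' The leftmost character is the most significant bit.
#'
#' @param bits character vector of 0/1 strings, all of the same length.
#' @return integer vector of indices in `[0, 2^L)`.
#' @examples
#' canonical_index(c("00", "11", "101"))  # 0, 3 -- and an error for "101"
#' @export
canonical_index <- function(bits) {
  bits <- as.character(bits)
  if (length(bits) == 0L) stop("empty input")
  len <- unique(nchar(bits))
  if (length(len) != 1L)
    stop("genotype strings have mixed lengths: ", paste(len, collapse = ", "))
  if (any(grepl("[^01]", bits)))
    stop("genotype strings must contain only 0 and 1")
  chars <- matrix(as.integer(strsplit(paste(bits, collapse = ""), "")[[1]]),
                  nrow = length(bits), ncol = len, byrow = TRUE)
  as.integer(chars %*% 2^((len - 1):0))
}

#' Genotype strings for all indices, in canonical order
#'
#' @param L number of loci.
#' @return character vector of `2^L` bitstrings, index 0 first.
#' @export
genotype_strings <- function(L) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  g <- 0:(2^L - 1L)
  bits <- vapply(
    (L - 1L):0,
    function(b) as.integer(bitwAnd(bitwShiftR(g, b), 1L)),
    integer(length(g)))
  apply(bits, 1L, paste, collapse = "")
}

#' Read a landscape from delimited text
#'
#' Expects a header and one row per genotype, with a 0/1 genotype string
#' column and a fitness column; optional variance and replicate-count
#' columns. Rows may be in any order; they are sorted into canonical
#' ascending-binary order. Completeness (all `2^L` genotypes present exactly
#' once) is enforced.
#'
#' @param path file path. `.csv` is read comma-separated, anything else
#'   tab-separated unless `sep` is given.
#' @param genotype_col,fitness_col,variance_col,n_col column names.
#' @param sep field separator, overriding the extension-based default.
#' @return a [landscape].
#' @export
read_landscape <- function(path, genotype_col = "genotype",
                           fitness_col = "fitness",
                           variance_col = "variance", n_col = "n",
                           sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  for (col in c(genotype_col, fitness_col))
    if (!col %in% names(tab)) stop("missing column '", col, "' in ", path)
  geno <- tab[[genotype_col]]
  idx <- canonical_index(geno)
  L <- nchar(geno[1L])
  if (anyDuplicated(idx))
    stop("duplicate genotypes: ",
         paste(unique(geno[duplicated(idx)]), collapse = ", "))
  missing <- setdiff(0:(2^L - 1L), idx)
  if (length(missing))
    stop("incomplete landscape; absent genotypes: ",
         paste(genotype_strings(L)[missing + 1L], collapse = ", "))
  ord <- order(idx)
  W <- as.numeric(tab[[fitness_col]])[ord]
  var <- if (variance_col %in% names(tab))
    as.numeric(tab[[variance_col]])[ord]
  nrep <- if (n_col %in% names(tab)) as.integer(tab[[n_col]])[ord]
  landscape(W, var = var, nrep = nrep, meta = paste("read from", path))
}

#' Write a landscape as delimited text
#'
#' Inverse of [read_landscape()]: genotype, fitness, and (when present)
#' variance and n columns, in canonical order.
#'
#' @param ls a [landscape].
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @param sep optional separator override.
#' @export
write_landscape <- function(ls, path, sep = NULL) {
  stopifnot(inherits(ls, "landscape"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(genotype = genotype_strings(ls$L), fitness = ls$W)
  if (!is.null(ls$var)) out$variance <- ls$var
  if (!is.null(ls$nrep)) out$n <- ls$nrep
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Slice a multi-allelic table down to a biallelic landscape
#'
#' For every locus carrying more than two observed alleles, two alleles are
#' drawn uniformly at random (seeded) and the table is restricted to rows
#' using only chosen alleles. The surviving genotypes are recoded as
#' bitstrings: at each locus the lexicographically smaller allele label
#' becomes 0. The result must be combinatorially complete; if the drawn
#' slice is not, an error is raised and the caller decides whether to
#' re-draw with another seed.
#'
#' @param table data.frame with a genotype-string column (one character per
#'   locus, arbitrary allele labels) and a fitness column; optional variance
#'   and replicate-count columns as in [read_landscape()].
#' @param seed integer seed for the allele draws.
#' @param genotype_col,fitness_col,variance_col,n_col column names.
#' @return a [landscape]; chosen alleles are recorded in `meta`.
#' @export
slice_biallelic <- function(table, seed, genotype_col = "genotype",
                            fitness_col = "fitness",
                            variance_col = "variance", n_col = "n") {
  geno <- as.character(table[[genotype_col]])
  len <- unique(nchar(geno))
  if (length(len) != 1L) stop("genotype strings have mixed lengths")
  L <- len
  chars <- matrix(strsplit(paste(geno, collapse = ""), "")[[1]],
                  nrow = nrow(table), ncol = L, byrow = TRUE)
  set.seed(seed)
  chosen <- vector("list", L)
  for (j in seq_len(L)) {
    alleles <- sort(unique(chars[, j]))
    if (length(alleles) < 2L)
      stop("locus ", j, " has fewer than 2 observed alleles")
    chosen[[j]] <- if (length(alleles) == 2L) alleles else sort(sample(alleles, 2L))
  }
  keep <- rep(TRUE, nrow(table))
  for (j in seq_len(L)) keep <- keep & chars[, j] %in% chosen[[j]]
  if (!any(keep)) stop("chosen slice is empty")
  sub <- chars[keep, , drop = FALSE]
  bits <- vapply(seq_len(L),
                 function(j) as.integer(sub[, j] == chosen[[j]][2L]),
                 integer(sum(keep)))
  idx <- as.integer(bits %*% 2^((L:1) - 1L))
  if (anyDuplicated(idx)) stop("duplicate genotypes within the chosen slice")
  missing <- setdiff(0:(2^L - 1L), idx)
  if (length(missing))
    stop("chosen slice is incomplete; absent genotypes: ",
         paste(genotype_strings(L)[missing + 1L], collapse = ", "),
         " (re-draw with another seed if desired)")
  ord <- order(idx)
  W <- as.numeric(table[[fitness_col]][keep])[ord]
  var <- if (variance_col %in% names(table))
    as.numeric(table[[variance_col]][keep])[ord]
  nrep <- if (n_col %in% names(table))
    as.integer(table[[n_col]][keep])[ord]
  meta <- paste0("biallelic slice (seed ", seed, "): ",
                 paste(vapply(chosen, paste, "", collapse = "/"),
                       collapse = ", "))
  landscape(W, var = var, nrep = nrep, meta = meta)
}
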