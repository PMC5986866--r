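#' Run the full decomposition pipeline on one landscape
#'
#' Executes, in order: optional log transform of the fitness scale; the
#' Walsh decomposition; magnitude ranking and the best-m residual-variance
#' sequence; truncation by the experimental-variance fraction when
#' per-genotype variances are present; Kendall's tau-b between the
#' observed sequence of epistatic orders and the combinatoric expectation;
#' and the permutation test of that correlation. The result is fully
#' determined by the input and `seed`.
#'
#' @param input a [landscape], or a file path readable by
#'   [read_landscape()].
#' @param log_transform log-transform the fitness scale first?
#' @param zero_fill substitute for `log(0)` (see
#'   [log_transform_landscape()]).
#' @param n_reps permutation replicates for the null distribution.
#' @param seed RNG seed for the permutation test.
#' @param zero_tol ranking tie tolerance (see [rank_terms()]).
#' @param name study label used in reports.
#' @return object of class `study_result`: list with `name`, `L`,
#'   `n_maxima`, `tau_b`, `p_uncorrected`, `p_corrected` (`NA` until a set
#'   is assembled), `n_terms`, `m_star`, `j`, `n_reps`, `seed`,
#'   `exp_var_fraction`, plus the intermediate `landscape`, `spectrum`,
#'   `approx` (an `approx_sequence`), and `per_order` table.
#' @examples
#' sim <- generate_nk(4, 1, seed = 2)
#' run_study(sim$landscape, n_reps = 2000, seed = 9)
#' @export
run_study <- function(input, log_transform = FALSE, zero_fill = -2,
                      n_reps = 1e5, seed = 1, zero_tol = NULL,
                      name = NULL) {
  ls <- if (inherits(input, "landscape")) input else read_landscape(input)
  if (is.null(name))
    name <- if (is.character(input)) basename(input)
            else if (!is.null(ls$meta)) ls$meta else "landscape"
  if (log_transform) ls <- log_transform_landscape(ls, zero_fill = zero_fill)
  evf <- if (!is.null(ls$var)) experimental_variance_fraction(ls)
  seq <- residual_sequence(ls,
                           exp_var_fraction = evf$exp_var_fraction,
                           zero_tol = zero_tol)
  m_star <- seq$m_star
  if (m_star < 2L)
    stop("truncation retained fewer than 2 terms; nothing to test")
  observed <- seq$ranked_orders[seq_len(m_star)]
  pt <- permutation_test(observed, ls$L, n_reps = n_reps, seed = seed)
  structure(list(name = name, L = ls$L,
                 n_maxima = count_maxima(ls),
                 tau_b = pt$tau_b,
                 p_uncorrected = pt$p_uncorrected,
                 p_corrected = NA_real_,
                 n_terms = pt$n_terms,
                 m_star = m_star, j = as.integer(2^ls$L - m_star),
                 n_reps = n_reps, seed = seed,
                 exp_var_fraction = evf$exp_var_fraction,
                 landscape = ls, spectrum = seq$spectrum, approx = seq,
                 per_order = per_order_summary(seq)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  p <- if (x$p_uncorrected == 0) paste0("< ", format(1 / x$n_reps))
       else format(x$p_uncorrected)
  cat("Study:", x$name, "\n")
  cat("  L =", x$L, "| maxima =", x$n_maxima,
      "| terms retained =", x$m_star, "of", 2^x$L, "\n")
  cat("  tau_b =", format(x$tau_b, digits = 4), "| one-tailed P =", p, "\n")
  if (!is.null(x$exp_var_fraction))
    cat("  experimental variance fraction =",
        format(x$exp_var_fraction, digits = 4), "\n")
  invisible(x)
}

# significance stars at the conventional thresholds, from corrected P
p_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "")))
}

#' Run and summarise a set of studies
#'
#' Applies [run_study()] to each input (or accepts pre-computed
#' `study_result` objects), Holm-corrects the uncorrected P values, and --
#' for sets of at least two studies -- tests the P values for uniformity
#' with [g_test_uniformity()]. Stars are computed from Holm-corrected
#' values while the table reports uncorrected P.
#'
#' @param inputs list of landscapes, file paths, or `study_result`s.
#' @param ... arguments passed to [run_study()] for inputs that still need
#'   running.
#' @param bin_edges G-test bin edges (see [g_test_uniformity()]).
#' @return object of class `study_set`: list with `table` (one row per
#'   study: name, L, n_maxima, m_star, tau_b, p_uncorrected, p_holm,
#'   stars), `g_test` (`NULL` for a single study), and `studies`.
#' @export
run_study_set <- function(inputs, ...,
                          bin_edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  if (length(inputs) == 0L) stop("empty study set")
  studies <- lapply(inputs, function(x)
    if (inherits(x, "study_result")) x else run_study(x, ...))
  p <- vapply(studies, `[[`, numeric(1), "p_uncorrected")
  ph <- holm_correct(p)
  for (i in seq_along(studies)) studies[[i]]$p_corrected <- ph[i]
  tab <- data.frame(
    name = vapply(studies, `[[`, character(1), "name"),
    L = vapply(studies, `[[`, integer(1), "L"),
    n_maxima = vapply(studies, `[[`, integer(1), "n_maxima"),
    m_star = vapply(studies, function(s) as.integer(s$m_star), integer(1)),
    tau_b = vapply(studies, `[[`, numeric(1), "tau_b"),
    p_uncorrected = p,
    p_holm = ph,
    stars = p_stars(ph))
  g <- if (length(studies) > 1L) g_test_uniformity(p, bin_edges = bin_edges)
  structure(list(table = tab, g_test = g, studies = studies),
            class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat("Study set:", nrow(x$table), "landscapes\n")
  tab <- x$table
  tab$tau_b <- format(tab$tau_b, digits = 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$g_test)) print(x$g_test)
  invisible(x)
}

#' Write a study-set report
#'
#' Delimited table mirroring the per-study summary (one row per study)
#' followed by a commented G-test summary line; or a JSON document when
#' `path` ends in `.json`.
#'
#' @param set a `study_set`.
#' @param path output path (`.csv`, `.tsv`, or `.json`).
#' @export
write_study_report <- function(set, path) {
  stopifnot(inherits(set, "study_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- list(studies = set$table)
    if (!is.null(set$g_test))
      out$g_test <- set$g_test[c("G", "df", "p_value")]
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(set$table, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(set$g_test))
    cat(sprintf("# G = %.6g, df = %d, P = %.4g\n",
                set$g_test$G, set$g_test$df, set$g_test$p_value),
        file = path, append = TRUE)
  invisible(path)
}
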