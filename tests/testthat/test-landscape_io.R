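test_that("canonical_index maps bitstrings with leftmost char as high bit", {
  expect_identical(canonical_index("00"), 0L)
  expect_identical(canonical_index("11"), 3L)
  expect_identical(canonical_index("101"), 5L)
  expect_error(canonical_index(c("01", "001")), "mixed lengths")
  expect_error(canonical_index("0a"), "only 0 and 1")
})

test_that("canonical_index is a bijection onto 0..2^L-1", {
  for (L in 1:4) {
    idx <- canonical_index(genotype_strings(L))
    expect_identical(sort(idx), 0:(2^L - 1L))
  }
})

test_that("landscape constructor validates shapes and values", {
  expect_error(landscape(1:3), "power of two")
  expect_error(landscape(1:4, var = c(1, 2)), "length")
  expect_error(landscape(1:4, var = c(1, 2, -1, 0)), "nonnegative")
  expect_error(landscape(1:4, nrep = c(1, 1, 0, 1)), "positive")
  ls <- landscape(c(0, 1, 2, 3))
  expect_identical(ls$L, 2L)
})

test_that("read_landscape reorders file rows into canonical order", {
  f <- tempfile(fileext = ".tsv")
  write_raw_landscape(f, c("11", "10", "01", "00"), c(3, 2, 1, 0))
  ls <- read_landscape(f)
  expect_identical(ls$L, 2L)
  expect_equal(ls$W, c(0, 1, 2, 3))
})

test_that("read_landscape rejects incomplete, duplicated, ragged input", {
  f <- tempfile(fileext = ".tsv")
  write_raw_landscape(f, c("11", "01", "00"), c(3, 1, 0))
  expect_error(read_landscape(f), "10")   # names the absent genotype
  write_raw_landscape(f, c("11", "01", "01", "00"), c(3, 1, 1, 0))
  expect_error(read_landscape(f), "duplicate")
  write_raw_landscape(f, c("01", "001"), c(0, 1))
  expect_error(read_landscape(f), "mixed lengths")
})

test_that("write then read is the identity on L, W, var, nrep", {
  set.seed(41)
  for (ext in c(".tsv", ".csv")) {
    ls <- landscape(runif(8), var = runif(8), nrep = rep(3L, 8))
    f <- tempfile(fileext = ext)
    write_landscape(ls, f)
    back <- read_landscape(f)
    expect_identical(back$L, ls$L)
    expect_equal(back$W, ls$W)
    expect_equal(back$var, ls$var)
    expect_equal(back$nrep, ls$nrep)
  }
})

test_that("slice_biallelic reduces a 3-allele locus to a complete slice", {
  # 3 alleles (a, b, c) at locus 1 x biallelic locus 2: 6 genotypes
  tab <- expand.grid(a1 = c("a", "b", "c"), a2 = c("0", "1"),
                     stringsAsFactors = FALSE)
  tab$genotype <- paste0(tab$a1, tab$a2)
  tab$fitness <- seq_len(nrow(tab))
  for (s in 1:5) {
    ls <- slice_biallelic(tab, seed = s)
    expect_identical(ls$L, 2L)
    expect_length(ls$W, 4L)
    expect_match(ls$meta, "seed")
  }
  # all 3 possible allele pairs at locus 1 give a complete slice, and the
  # drawn pair always is one of them
  pairs <- combn(c("a", "b", "c"), 2)
  seen <- unique(vapply(1:20, function(s)
    sub(".*: ", "", slice_biallelic(tab, seed = s)$meta), ""))
  for (m in seen)
    expect_true(strsplit(m, ", ")[[1]][1] %in% apply(pairs, 2, paste, collapse = "/"))
})

test_that("slice_biallelic passes biallelic tables through unchanged", {
  tab <- data.frame(genotype = c("00", "01", "10", "11"),
                    fitness = c(0, 1, 2, 3))
  ls <- slice_biallelic(tab, seed = 1)
  expect_equal(ls$W, c(0, 1, 2, 3))
})

test_that("slice_biallelic reports an incomplete slice instead of redrawing", {
  tab <- expand.grid(a1 = c("a", "b", "c"), a2 = c("0", "1"),
                     stringsAsFactors = FALSE)
  tab$genotype <- paste0(tab$a1, tab$a2)
  tab$fitness <- seq_len(nrow(tab))
  tab <- tab[tab$genotype != "a0", ]   # drop one combination
  hit <- FALSE
  for (s in 1:20) {
    res <- tryCatch(slice_biallelic(tab, seed = s), error = identity)
    if (inherits(res, "error")) {
      hit <- TRUE
      expect_match(conditionMessage(res), "incomplete")
    }
  }
  expect_true(hit)   # the a-containing slices must fail
})
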