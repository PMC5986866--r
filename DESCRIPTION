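Package: walshscape
Title: Walsh Decomposition and Topographic Analysis of Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing combinatorially complete fitness landscapes
    over biallelic loci. Landscapes are decomposed into epistatic interaction
    terms of every order with the Fourier-Walsh (Hadamard) transform, terms are
    ranked by their contribution to landscape topography via best-m subsetting
    approximations, and the hypothesis that epistatic influence declines with
    interaction order is tested with Kendall's tau-b against the combinatoric
    expectation, a permutation null, Bonferroni-Holm correction, and a
    cross-dataset G-test of P-value uniformity. Includes a Kauffman NK
    landscape simulator, local-maxima counting, fitness-scale preprocessing
    (log transforms with Taylor moment propagation, confidence-interval to
    variance conversion), and synthetic-landscape generators with controlled
    per-order coefficient decay and Gaussian measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
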