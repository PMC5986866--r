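# walshscape

Analysis of combinatorially complete fitness landscapes: how much does
epistasis of each order shape landscape topography?

A combinatorially complete dataset measures a fitness proxy (growth rate,
MIC, IC50, replicative capacity, ...) for all `2^L` genotypes over `L`
biallelic loci. `walshscape` decomposes such a landscape into its `2^L`
epistatic interaction terms with the Fourier–Walsh (Hadamard) transform

```
E = Psi W / 2^L,          W = Psi E,          Psi^2 = 2^L I,
```

where the set bits of index `k` name the loci interacting in term `E_k`
and `popcount(k)` is its *epistatic order* (0 = mean, 1 = main effects,
≥ 2 = genuine epistasis). Because the transform is orthogonal, keeping
the `m` largest-magnitude terms gives the provably best `m`-parameter
approximation of the landscape, and the squared magnitude of each term is
exactly its contribution to the variance of fitness across the landscape.

The package then asks whether that contribution *declines with order*:
it compares the orders of the magnitude-ranked terms against the
combinatoric expectation (one 0, `L` ones, `choose(L,2)` twos, ...) with
Kendall's tie-corrected `tau_b`, attaches a one-tailed permutation `P`
(null: random permutations of the expectation multiset on both sides),
Holm-corrects across studies, and G-tests a set of studies' `P` values for
uniformity. Supporting machinery includes per-genotype experimental
variances (Taylor-propagated log transforms, CI-to-variance conversion,
variance-based truncation of the ranked sequence), a Kauffman NK
landscape simulator with local-maxima counting, and synthetic-landscape
generators with controlled per-order coefficient decay and Gaussian
measurement noise, so that every stage is testable without external data.

Intended users: evolutionary geneticists and biophysicists working with
combinatorially complete genotype–fitness data (typically `L ≤ 16`).

## Worked example

Simulate a five-locus NK landscape with moderate epistasis (`K = 2`) and
run the full pipeline:

```r
library(walshscape)
sim <- generate_nk(5, 2, seed = 11)
st  <- run_study(sim$landscape, n_reps = 1e5, seed = 12, name = "NK N=5 K=2")
st
#> Study: NK N=5 K=2
#>   L = 5 | maxima = 1 | terms retained = 32 of 32
#>   tau_b = 0.6788 | one-tailed P = < 1e-05
```

`tau_b = 0.6788` says the magnitude ranking of the 32 epistatic terms is
strongly concordant with the low-orders-first expectation, and no random
ordering among 10^5 reached it (`P < 1e-05`). The per-order attribution
shows where the variance lives:

```r
per_order_summary(st$approx)
#>   order aggregate_reduction n_terms mean_reduction
#> 1     0        0.000000e+00       1   0.000000e+00
#> 2     1        6.206822e-01       5   1.241364e-01
#> 3     2        2.805944e-01      10   2.805944e-02
#> 4     3        9.872340e-02      10   9.872340e-03
#> 5     4        8.591218e-33       5   1.718244e-33
#> 6     5        5.403282e-35       1   5.403282e-35
```

Main effects explain 62% of the variance about the mean, pairwise terms
28%, and the per-term mean reduction falls by roughly an order of
magnitude per order (orders 4–5 are numerically zero: no neighbourhood
couples those loci). Sweeping `K` shows topography roughening and the
order signal dissolving as epistasis intensifies:

```r
run_study_set(lapply(0:4, function(K)
  run_study(generate_nk(5, K, seed = 11)$landscape, n_reps = 2e4,
            seed = 12 + K, name = paste0("NK K=", K))))
#> Study set: 5 landscapes
#>    name L n_maxima m_star    tau_b p_uncorrected p_holm stars
#>  NK K=0 5        1     32  0.73575       0.00000 0.0000   ***
#>  NK K=1 5        2     32  0.79534       0.00000 0.0000   ***
#>  NK K=2 5        1     32  0.67876       0.00000 0.0000   ***
#>  NK K=3 5        5     32  0.37824       0.00485 0.0097    **
#>  NK K=4 5       10     32 -0.02073       0.55810 0.5581
#> G-test of P-value uniformity: G = 69.2066 , df = 5 , P = 1.499e-13
```

Empirical tables are read with
`read_landscape("file.tsv")` (columns `genotype`, `fitness`, optional
`variance`, `n`); `run_study(path, log_transform = TRUE)` handles
log-scale proxies, and landscapes with per-genotype variances are
automatically truncated where the remaining model variance drops below
the experimental variance.

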