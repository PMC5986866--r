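---
title: "Decomposing fitness landscape topography by epistatic order"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing fitness landscape topography by epistatic order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walshscape)
```

## The model

A combinatorially complete dataset assigns a fitness value (or a proxy such
as a growth rate or an MIC) to every one of the $2^L$ genotypes formed by
$L$ biallelic loci. Arranged in canonical order — ascending $L$-bit binary,
bit $b$ set when the mutation at locus $b$ is present — the fitness vector
$\vec W$ is an element of $\mathbb{R}^{2^L}$, and the Hadamard matrix
$\Psi$ (Sylvester construction, $\Psi_{jk} = (-1)^{\mathrm{popcount}(j
\wedge k)}$) provides an orthogonal basis of interaction contrasts:

$$\vec E = \frac{1}{2^L}\,\Psi\,\vec W, \qquad \vec W = \Psi\,\vec E .$$

Component $E_k$ is the epistatic term for the subset of loci named by the
set bits of $k$; its *order* is $\mathrm{popcount}(k)$. Order 0 is the mean
fitness, order 1 the main effects, order $\ge 2$ genuine epistasis. Because
$\Psi^2 = 2^L I$, Parseval's identity ties the geometry of the two spaces
together: the population variance of $\vec W$ about its mean equals
$\sum_{k \neq 0} E_k^2$.

Two conventions are fixed once and documented rather than configurable:

* **Bit order.** In genotype strings the leftmost character is the
  highest-order bit. Every statistic computed here is invariant to locus
  permutation, but individual coefficient identities are not, so
  cross-checking single coefficients against other software may require a
  locus relabelling.
* **Signs.** With the all-zeros string as reference genotype, the sign of
  an individual term depends on which allele is coded 0 (at sliced
  multi-allelic loci the lexicographically smaller allele label). Only
  magnitudes and orders feed the downstream statistics.

## Ranking terms and best-$m$ approximations

Zeroing all but a subset of the components of $\vec E$ and inverting gives
a *subsetting approximation* of the landscape. Orthogonality makes the
best choice trivial: for any $m$, keeping the $m$ components of largest
absolute value minimises the sum-of-squares distance to $\vec W$ over all
$\binom{2^L}{m}$ alternatives (the test suite confirms this by exhaustive
enumeration at $L = 2, 3$). The *residual sequence* records, for
$m = 0, \dots, 2^L$, the unexplained fraction of variance about the mean:
the sum of squared excluded non-zeroth terms over the sum of all
non-zeroth squared terms. Expressing residuals as fractions of variance
*about the mean* means the order-0 term never "explains" anything, which
keeps per-order attributions comparable across landscapes.

**Tie-breaking.** Coefficients of equal magnitude are ranked by ascending
canonical index, a stable and deterministic rule. In floating point,
coefficients that are structurally zero (for instance, every order
$\ge 2$ term of an additive landscape) come out of the transform as
round-off residue near $10^{-17}$, which would otherwise be ranked in an
arbitrary noise order. `rank_terms()` therefore snaps magnitudes at or
below a tolerance of $8 \cdot 2^L \varepsilon \max_k |E_k|$ — the scale of
accumulated transform round-off, far below any empirically meaningful
term — to exactly zero before sorting. With this rule the pipeline
statistic for an additive five-locus landscape is the same for every seed:
$\tau_b = 284/386 \approx 0.7358$.

**Truncation by experimental variance.** When per-genotype variances are
available, the pooled experimental variance (unweighted mean across
genotypes; pooling is a package choice, as is the population $1/2^L$
variance convention that matches the Parseval bookkeeping) is expressed as
a fraction of model variance, and the ranked sequence is cut at the
smallest $m$ whose remaining model variance falls below it. An
alternative, element-wise reading — discard every individual term whose
own contribution is below the experimental variance — differs whenever a
small term precedes a large one in rank; the cumulative rule is
implemented because truncation is a statement about the remaining signal,
not about single terms. A threshold of 0 truncates where the residual
first vanishes; thresholds at or above the total variance retain nothing
and warn.

## Testing for declining influence

If epistatic influence declines with order, the orders of the
magnitude-ranked terms should approximate the sorted multiset

$$0, \underbrace{1, \dots, 1}_{L}, \underbrace{2, \dots, 2}_{\binom L2},
\dots, L ,$$

and agreement is measured with Kendall's $\tau_b$, whose tie corrections
matter because both sequences are heavily tied. The implementation works
from the joint contingency table ($O(c^2)$ for $c$ distinct values after
tabulation), is checked against a brute-force $O(n^2)$ pair counter and
`stats::cor(method = "kendall")`, and is fast enough to drive dense
permutation nulls.

The null distribution permutes the expectation multiset *on both sides*:
each replicate draws two independent uniform permutations and records
their $\tau_b$. The one-tailed $P$ is the fraction of null draws at or
above the empirical value; when none qualifies the stored value is 0 and
the print method reports `< 1/n_reps`. With the expectation multiset fixed
on both sides the tie-corrected denominator is constant, so only the
concordance numerator is recomputed per replicate. For $L = 2$ the null
is small enough to enumerate: $P(\tau_b = 1) = 1/12$, which the sampled
test reproduces within Monte-Carlo error.

Across a set of studies, Holm's step-down correction guards the
individual calls, and a likelihood-ratio $G$-test checks the uncorrected
$P$ values against uniformity. The default binning uses six log-decade
bins with edges at $10^{-5}, \dots, 10^{-1}$ (hence 5 degrees of
freedom); the lowest bin is closed at zero so that censored
"less than" bounds and exact-zero permutation estimates land there.
$G$ is moderately sensitive (a few percent) to the exact edges, which is
why the acceptance check on a published set of 16 $P$ values is a band
rather than a point.

## Preprocessing choices

* Growth-rate and resistance proxies are analysed on the natural-log
  scale. Zero measurements have no log; they are filled with $-2$ by
  default, roughly one log order below typical smallest nonzero values,
  and overridable.
* When only means and variances are reported, log-scale moments use the
  Taylor rules $\overline{\ln x} \approx \ln\bar x - s^2/(2\bar x^2)$ and
  $s^2_{\ln x} \approx (s/\bar x)^2$; zero-fitness genotypes get log-scale
  variance 0, since nothing survives the fill value.
* `ci95_to_variance()` implements $s^2 = (n \cdot CI95/1.96)^2$ literally,
  *with* the $n$ multiplier. The conventional back-calculation would use
  $\sqrt n$; the literal form is kept, and documented, so that analyses
  built on it are reproducible as published elsewhere rather than
  silently "corrected".

## The NK simulator

The simulator follows the standard Kauffman formulation: each locus
contributes a value read from its own table of $2^{K+1}$ i.i.d.
$U[0,1)$ entries, indexed by its own allele and those of $K$ uniformly
drawn distinct neighbours, and genotype fitness is the *mean* of the $N$
contributions. Neither the contribution distribution nor mean-vs-sum
aggregation affects the rank statistics or maxima counts; the mean keeps
the order-0 term near $0.5$ and dominant, as in empirical proxy scales.
Local maxima require *strictly* higher fitness than all $L$ neighbours;
plateau ties are warned about and not counted, because silently counting
(or double-counting) flat regions would corrupt topography summaries.

One subtlety matters for calibration claims. In the maximally epistatic
limit $K = N - 1$ the $2^N$ fitness values are i.i.d., and one might
expect the pipeline's $\tau_b$ to average zero. It does not, quite: the
order-0 term $E_0 \approx 0.5$ dominates every other coefficient almost
surely, always ranks first, and is concordant with the expectation's
leading zero, giving $\mathbb{E}[\tau_b] = (2^N - 1)/386 \approx 0.080$
for $N = 5$ while the remaining terms contribute nothing on average. The
test suite asserts this derived offset, not zero. A genuinely centred
negative control requires *all* coefficients i.i.d., which
`decaying_spectrum(..., e0 = NULL)` provides.

## Synthetic landscapes

`decaying_spectrum()` draws $E_k \sim N(0, \sigma_{o(k)}^2)$ with one
scale per order, the order-0 term pinned to 1 by default (mirroring
empirical landscapes, where mean fitness dominates). Geometric decay
$\sigma_o = 2^{-o}$ emulates the declining-influence structure the
pipeline is designed to detect; a constant scale with `e0 = NULL` gives
the fully i.i.d. spectrum of the maximally rugged limit.
`landscape_from_spectrum()` adds a measurement layer: each genotype's
reported fitness is the mean of `n_reps` Gaussian draws and its reported
variance the sample variance, so experimental-variance truncation is
exercised end to end. Error propagation through the orthogonal transform
gives each recovered coefficient a standard error of
$\sigma_{\text{noise}}/\sqrt{n_{\text{reps}} \cdot 2^L}$, which the tests
verify by simulation.

What the generators do *not* emulate: nonlinear measurement scales
(monotone warping of the fitness proxy), heteroscedastic or correlated
noise across genotypes, replicate counts varying by genotype, and
missing genotypes. Passing tests on synthetic data therefore demonstrate
the pipeline's correctness and calibration under Gaussian, independent
noise on a fixed scale — not robustness to scale misspecification, which
is a known limitation of magnitude-based epistasis analysis in general.

## Problem sizes and numerical tolerances

The test suite runs at sizes chosen to make every claim checkable by
enumeration or by stable Monte-Carlo: exhaustive subset optimality at
$L \le 3$ (20 random landscapes each), exhaustive permutation nulls at
$L = 2$, sampled nulls of $10^5$ replicates at $L = 5$, 500 null studies
of 2000 replicates for uniformity calibration, and 100–200 replicate
batches for the directional controls. Transform identities are asserted
at $10^{-10}$–$10^{-12}$; Monte-Carlo assertions use 2–3 standard-error
bands derived from the quantity being measured.

## Known limitations

* Everything is $O(2^L)$ in memory and time; the design targets the
  $L \le 16$ regime of combinatorially complete experiments.
* Loci with more than two alleles are handled only by slicing down to two
  (seeded, recorded in `meta`), not by a higher-cardinality transform.
* The permutation test conditions on the truncation point rather than
  propagating uncertainty in it; experimental noise in the coefficient
  magnitudes themselves is likewise not propagated into the ranking.
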