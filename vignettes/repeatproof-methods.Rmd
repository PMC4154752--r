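---
title: "Methods: assembly evaluation for genes and transposable elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly evaluation for genes and transposable elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, and the numerical decisions behind `repeatproof`. The package
evaluates a draft assembly against a trusted reference, so every observed
discrepancy must be *attributed*: to the reads (coverage gaps), to the
assembler (misassembly, collapse), or to the sample (residual
heterozygosity). Each section below states the model, the parameter
defaults, and why.

## 1. Best placement of contigs

A contig's local alignments to the reference usually include spurious
repeat-induced hits. Mirroring `delta-filter`-style best-query filtering,
`best_placement()` selects the subset of blocks that is non-overlapping in
contig coordinates — pairwise overlap at most `overlap_tolerance` bases, 50
by default, to absorb alignment-end jitter — and maximizes
$\sum_i \text{identity}_i \cdot \text{alignedlength}_i$.

This is solved exactly as weighted interval scheduling after a coordinate
transform: two blocks overlap by more than $t$ bases **iff** their intervals
shrunk by $t/2$ at each end still intersect. The shrink is done in doubled
integer coordinates so no fractions appear. Blocks whose contig span is at
most $t$ shrink away entirely; they are compatible with every other block
and always selected. Ties are broken toward fewer blocks. The test suite
checks the DP against exhaustive subset search over all $2^n$ subsets for
500 random instances — this oracle caught a genuine bug in an earlier
right-end-only shrink, which cannot represent short nested blocks.

Reference-side overlaps between selected blocks are deliberately allowed
(duplications in the draft should surface in the duplication ratio, not be
filtered away).

## 2. Feature assessment

A feature (gene or TE copy, 0-based half-open `[start, end)`) is

* **contained** when both boundary bases `start` and `end − 1` lie inside
  aligned blocks of a single contig's placement chain;
* **perfect** when, additionally, a local realignment of the feature against
  its projected contig interval has identity 1 and covers every feature base;
* **partial** when not contained but a boundary, or ≥ 100 bp of the feature,
  is covered by some block.

For contained features the feature span plus 100 bp of flanking context is
extracted from both sequences and realigned locally with megablast-like
scoring (match +2, mismatch −3, gap open 5, gap extend 2). Identity and
length ratio are computed **only over alignment columns inside the feature
interval**; the flanks merely anchor the alignment at the feature edges so a
mismatch at the first feature base cannot be silently trimmed away.

## 3. Read error decomposition

For highly accurate reads aligned to a trusted reference, mismatch sites
have two sources: sequencing error and residual heterozygosity of the
sequenced inbred line. With $M$ = number of reference sites carrying at
least one mismatch observation, $L$ = reference length, $h$ = fraction of
the genome still segregating in the line, $\pi$ = pairwise diversity within
those regions, and $c$ = mean depth:

$$ M/L = e_{\text{site}} + h\pi, \qquad e_{\text{read}} = e_{\text{site}}/c. $$

When $h$ is unknown, a known-SNP site list identifies it: with $p$ the
fraction of sites that are known SNPs and $M_{\text{SNP}}$ the mismatch
sites overlapping them, $e_{\text{site}} = (M - M_{\text{SNP}})/(L(1-p))$,
under the conservative assumption that every segregating site has been
previously observed. `solve_error_rates()` implements both routes; the
division by $c$ converts the per-site rate to per read base because at error
rates this low, two independent errors at the same site are negligible
($O((ce_{\text{read}})^2)$). The package's simulator validates the whole
chain: heterozygous sites are planted at allele frequency 0.5, reads are
simulated, and the corrected estimator recovers the configured error rate
while the naive $M/(Lc)$ overshoots by $h\pi/c$ — the tests require the
corrected estimator to win in 20 of 20 seeds.

## 4. The TE assembly-success model

Whether a TE copy assembles perfectly is modeled as a random-intercept
logistic regression:

$$ \Pr(y_{ij} = 1 \mid u_j) = \operatorname{logit}^{-1}\!\big(\beta_0 +
\beta^\top z_{ij} + u_j\big), \qquad u_j \sim \mathcal N(0, \sigma^2), $$

with one intercept $u_j$ per TE family and predictors: copy length, GC of
the copy ±1 kbp of flank, divergence from the family canonical sequence,
the family's number of high-identity copies (divergence strictly < 0.01),
and the divergence × high-copies interaction. All predictors are
standardized; the interaction is the product of the standardized columns.

The marginal likelihood integrates out $u_j$ by a **Laplace approximation**
with an exact inner Newton step per family (the conditional posterior of a
one-dimensional random intercept is log-concave, so Newton converges
quadratically). The approximation is implemented from scratch and tested
three ways: (i) at $\sigma \to 0$ it equals the plain logistic
log-likelihood to 10⁻⁴; (ii) on a 3-family toy it matches a 51-point
Gauss–Hermite quadrature oracle (nodes from the eigendecomposition of the
Jacobi matrix, an independent implementation) to a relative 10⁻³; (iii) the
full fit matches `lme4::glmer` (which maximizes the same Laplace objective)
to 10⁻³ on coefficients, random-intercept SD, and Wald standard errors.
Optimization uses `nlminb` from fixed starting values ($\beta = 0$,
$\sigma = 1$) so fits are deterministic; a coefficient escaping beyond
|β| > 15 triggers a complete-separation error rather than a garbage fit
(the log-likelihood uses an overflow-safe `log(1+e^x)` so that guard is
actually reachable).

Expected signs, reproduced by the tests on fully synthetic pipeline output
with failures planted at long, low-divergence copies: $\beta_{\text{length}}
< 0$ (long copies exceed read length and break contigs) and
$\beta_{\text{divergence}} > 0$ (old, diverged copies are effectively
unique sequence and assemble easily).

## 5. The synthetic-data generator

The generator is the package's measurement standard: it plants structures
whose correct evaluation is known by construction.

* **Genome**: uniform-ish background sequence with a smoothly varying GC
  landscape, non-overlapping genes, and TE copies derived from a per-family
  canonical sequence by planting a drawn number of substitutions — so each
  copy's divergence is *exactly* `n_subs / length`, and a diverged feature's
  expected identity is known to the base. A configurable fraction of copies
  is inserted as adjacent tandem pairs, the structure that assemblers
  collapse.
* **Reads**: lengths from a two-component log-normal mixture (below),
  truncated at the 1.5 kbp minimum; mismatch/insertion/deletion events drawn
  per read as binomials at the configured per-base rates
  (defaults 0.0509%, 0.0166%, 0.0290%); an optional elevated mismatch rate
  over the first 100 read bases and a logistic GC-biased start-position
  weight mimic library artifacts. Alignments are emitted as ground truth in
  `=`/`X`/`I`/`D` run form, so the read evaluator can be tested without an
  external aligner.
* **Draft contigs**: exact reference segments broken at planted gap
  intervals, with optional tandem-pair collapses (one copy of a pair
  excised), relocations (segment order swaps), and base-level divergence
  noise. Every annotated feature receives a truth label — perfect,
  diverged (with exact planted identity), broken, or absent — and the tests
  require the assessor to reproduce those labels for 100% of features over
  20 seeds.

**Read-length mixture — deviation note.** The module contract suggested a
mixture with 80% of mass in a long component at median 0.9 × modal length.
That cannot reproduce the documented summary statistics (mean ≈ 4.4 kbp with
a hard 1.5 kbp minimum and a *local* mode at 8.5 kbp — i.e., most reads are
short): 80% of mass near 7.7 kbp forces a mean near 7 kbp. The implemented
law follows the substance: 75% short log-normal component
($\mu = \log 2400$, $s = 0.45$) + 25% long component (median 0.9 × modal
length, $s = 0.12$), truncated at the minimum by resampling. This yields
mean ≈ 4.4 kbp, a dominant short mass, and a secondary mode at ≈ 7.7 kbp.

## 6. Pseudo-assembly and coverage response

`pseudo_assemble()` simulates the contiguity an ideal assembler could reach
if coverage gaps were the only limitation: read placements merge
transitively when they overlap by ≥ 800 bp (a proxy for the minimum usable
overlap), and merged spans < 1 kbp are discarded. Pseudo-contigs are exact
reference segments, so "perfect feature recovery" reduces to interval
containment. `coverage_series()` downsamples one deep read set to a ladder
of depths **with the same seed**, which makes the subsets nested: coverage
only grows with depth, pseudo-contig spans only grow, and the perfect
fractions are non-decreasing per seed by construction. NG50 is non-
decreasing for a subtler reason and *not* deterministically: two
pseudo-contigs overlapping by < 800 bp double-count their overlap until a
deeper sample merges them, which can shrink the total near the NG50 target.
The tests therefore assert the NG50 trend empirically across seeds rather
than claiming it as an invariant.

## 7. Numerical choices

* All interval logic is integer, 0-based half-open; IRanges does the set
  arithmetic. The placement DP runs in doubled integer coordinates to keep
  the half-tolerance shrink exact.
* `per100kbp_errors()` compares equal-length block pairs gap-free (optimal
  under the +2/−3/5/2 scoring unless mismatches are pervasive) and realigns
  unequal pairs in 20 kbp tiles to respect the dynamic-programming matrix
  size limit; a gap run crossing a tile boundary counts as two events, a
  documented and negligible bias.
* The Laplace objective's inner Newton loop is vectorized over families via
  `rowsum`; the profiled term is $\ell_{\text{cond}} - \sum_j u_j^2/2\sigma^2
  - \tfrac12 \sum_j \log(1 + \sigma^2 W_j)$ with $W_j$ the summed Bernoulli
  weights of family $j$.
* The run report is serialized with `jsonlite` at full precision
  (`digits = NA`); reruns with the same config and seed are byte-identical.

## 8. Limitations

* The pseudo-assembly is a lower-bound surrogate for re-running an
  assembler; it cannot exhibit assembler-specific artifacts (chimeric joins,
  consensus errors).
* The heterozygosity correction assumes every segregating site is either
  known ($M_{\text{SNP}}$ route) or summarized by a single $h\pi$ product;
  structured residual heterozygosity (few large blocks) only affects the
  variance of the estimate, not its expectation.
* The GLMM uses a Laplace approximation; with very small families and
  $\sigma \gtrsim 1$ the approximation error grows (the quadrature oracle in
  the test suite bounds it at the tested regimes).
* The generator's background sequence is not a phylogenetic simulation;
  divergence is planted as independent substitutions, so indel-mediated TE
  decay is out of scope.
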