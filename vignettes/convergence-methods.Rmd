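---
title: "Methods: binary genus patterns, phi distances and family convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binary genus patterns, phi distances and family convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litterflora)
```

## The analysis model

The package analyses culture-based bacteriology of dam-litter units
around parturition. Each unit ("family") contributes samples at four
times — birth (T0) and days 2, 30 and 60 post-partum — from the dam
(rectal swabs at every time, vaginal swabs and mammary secretion at
T0/T2; the T0 mammary secretion is colostrum, the T2 one milk) and
from every puppy (a meconium rectal swab at T0, ordinary rectal swabs
afterwards). Culture plus MALDI-TOF identification yields, per sample,
a list of genera with an ordinal growth class.

All inference runs on **binary genus patterns**: the growth class and
the species string are retained as metadata but never weight the
pattern, because presence/absence is the only information culture
recovers consistently across media and plates. The genus universe is
**dataset-global** (the union over all samples, not per family), so
two samples from different families are compared over the same
coordinate system; shared absences are informative for the phi
coefficient exactly as concordant zeros are for a Pearson correlation.

### Distance

For two patterns the phi coefficient is the Pearson correlation of
the 0/1 vectors, computed from the 2×2 co-presence table. The package
maps it to a distance with d = (1 − φ)/2, which is bounded in [0, 1]
with d = 0 for identical non-constant patterns and d = 1 for
complementary ones. The choice between (1 − φ)/2 and 1 − φ is
immaterial for every conclusion the pipeline draws — heterogeneity
rankings, rank-sum p-values and linkage topologies are invariant under
affine transforms of the distance, which the test suite asserts — so
the bounded variant is the default and the other is an option.

Constant patterns (all-zero rows from sterile-looking samples, which
real meconium and colostrum data do produce) make φ undefined. The
default policy treats such pairs as uncorrelated (φ = 0, d = 0.5),
except that two identical constant rows are at distance 0; a strict
policy that aborts instead is available. Degenerate rows are reported
in the run log rather than silently absorbed.

### Convergence statistics

*Within-family heterogeneity* at a time point is the arithmetic mean
of all pairwise distances among that family's samples at that time
(undefined below two samples; such cells are kept with their counts).
Dam samples are pooled into the family set by default, since the unit
of analysis is the dam-litter unit; a flag excludes them. Two matrix
filters are provided: all samples, and rectal swabs only (meconium
included), the latter avoiding bias from mixing sample matrices.

Each later time point's per-family heterogeneities are compared to the
T0 values with the **exact Wilcoxon rank-sum test**: the null
distribution is enumerated over all C(n_a+n_b, n_a) assignments of the
observed mid-ranks, so ties are conditioned on exactly, and the
two-sided p doubles the smaller tail (capped at 1). The unpaired
rank-sum form is used rather than a signed-rank test, although
families recur across time points: with six families per group the
exact two-sided floor is 2/924 ≈ 0.0022, which is what a "p < 0.01 at
6 families" finding rests on. Enumeration is used whenever
C(n, n_a) ≤ 200,000 (always, at study scale); beyond that the test
falls back to the normal approximation with tie-corrected variance
and continuity correction. No multiplicity correction is applied by
default (three comparisons, reported raw); Holm adjustment is a flag.

*Complete-linkage dendrograms* are built per family from the same
distances. Complete linkage guarantees non-decreasing merge heights,
and the spanning height of a time point's leaf set (the height of the
lowest node containing it) quantifies how tightly those samples
cluster — converged T60 sets span lower than T0 sets. Ties in the
minimum-distance search are broken by the lexicographically smallest
pair of cluster indices in creation order, making runs
bit-reproducible; ties are measure-zero for real-valued data, so this
choice cannot affect substantive results. Heights inherit the [0, 1]
distance scale and are not rescaled. Trees export to Newick with
branch lengths chosen so each leaf-to-root path equals the root
height.

*Two-dimensional scaling* is classical Torgerson scaling per family:
B = −½·J·D⁽²⁾·J, coordinates from the two largest positive
eigenvalues, each axis scaled by √eigenvalue. Phi distances are not
guaranteed Euclidean, so negative eigenvalues can occur; they are
dropped without an additive-constant correction, and the goodness
statistic (retained positive eigenvalue mass over all positive mass)
reports how much structure two axes carry. If fewer than two positive
eigenvalues exist the missing axis is zero-filled. A deterministic
sign convention (each axis's largest-magnitude coordinate positive)
removes the reflection ambiguity. The ordination is per family, not
global: the dispersion question is within-family, and per-family
scaling avoids one family's structure distorting another's embedding;
areas remain comparable because all ordinations inherit the common
[0, 1] distance scale (with per-family 2D stress differing, which is
why goodness is reported alongside).

*Polygon areas*: the area covered by a time point's samples in the
2DS plane is the area of their **convex hull** (monotone-chain hull,
shoelace area). The hull is the canonical order-free reading of a
"polygon covered by the points"; fewer than three distinct
non-collinear points give area 0, which is recorded with its point
count rather than dropped. Per-family areas are pooled per time point
and T30/T60 are tested against T0 with the same exact rank-sum test.

## The synthetic generator

The generator emulates the design the statistics assume, not real
microbial ecology. Per family it draws a latent binary genus profile
(each genus present with probability 0.4, optionally forcing a shared
core); each sample is the profile with every genus independently
flipped at the time point's flip rate ε, and meconium samples
additionally lose each present genus with probability 0.5 (meconium
is markedly sparser in culture than later rectal swabs; dropout is the
simplest mechanism producing that without changing the underlying
profile). Defaults mirror the study shape: 6 families, litter sizes
8, 6, 4, 8, 7, 3 (each within 3–8), dams contributing all three
matrices, and the convergent flip schedule

| time | T0 | T2 | T30 | T60 |
|------|----|----|-----|-----|
| ε    | 0.40 | 0.30 | 0.15 | 0.10 |

The genus pool holds the twelve culturable genera characteristic of
the system (enterics, streptococci/enterococci, staphylococci,
clostridia, environmental genera). Growth classes are drawn uniformly
— they are metadata and never enter the analysis. The null preset
fixes ε = 0.25 at every time and removes meconium dropout, so all
time points are exchangeable and rejection rates measure type-I error
cleanly.

Two closed forms anchor the generator's calibration. Two samples of
one family disagree at a genus with probability 2ε(1−ε), so the mean
pairwise Hamming fraction h̄ of a family/time cell inverts to
ε̂ = (1 − √(1 − 2h̄))/2 (clipped to [0, 0.5]). The recovery harness
runs with meconium dropout off, because the inversion estimates the
flip rate alone and dropout is a second, separate noise source that
would bias the T0 cell upward.

What the generator does *not* model: genus covariance (flips are
independent), abundance, strain-level transmission, environmental
acquisition dynamics, or sample dropout over time. Passing the
Monte-Carlo suites therefore shows the pipeline detects convergence
of this form at study scale — it does not validate the biological
model of any real dataset.

## Numerical and design choices

- Exact-test enumeration uses `utils::combn` up to 200,000
  assignments (≈ C(20,10)); study-scale comparisons (6 vs 6, 924
  assignments) are always exact.
- Distance validation requires symmetry to 1e−8 and finite entries;
  MDS recovery of Euclidean-realizable inputs is tested to 1e−9.
- Ties: mid-ranks in the rank-sum test; creation-order tie-breaks in
  linkage; first-index tie-break in the MDS sign convention.
- Degenerate inputs (constant patterns, single-sample cells,
  sub-triangle polygons) are retained and logged, never errors: the
  real data provably contain them.
- Problem sizes used by the shipped Monte-Carlo analyses: 200
  replicates for power and parameter recovery, 500 for type-I, all at
  full study scale (~192 samples each). These sizes put the binomial
  uncertainty of an estimated 90% power at about ±2 percentage
  points.

## Known limitations

- Presence/absence at genus level discards abundance and species
  information by design; two samples dominated by different species
  of one genus are identical patterns.
- The unpaired rank-sum test ignores the pairing of families across
  time points; it is the conservative reading of a rank-sum design at
  n = 6.
- Per-family ordinations are not Procrustes-aligned, so coordinates
  (not areas) are incomparable across families.
- With twelve genera the phi coefficient is grainy; small-universe
  datasets will show discreteness in distances and heterogeneities.
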