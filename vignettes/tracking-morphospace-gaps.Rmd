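---
title: "Tracking morphospace gaps through time: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking morphospace gaps through time: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphogap)
```

This vignette documents the statistical model, every default setting
and why it was chosen, the synthetic data generators, and the
numerical conventions that make results reproducible bit for bit.

## 1. Model and assumptions

**Morphospace.** Species are points in a PCA space built from a trait
table. Traits are natural-log transformed — morphometric measurements
are ratio-scale and right-skewed — except traits named in
`log_exempt` (by default the hand-wing index, a dimensionless ratio in
[0, 1] for which a log adds nothing). Each trait is then z-scored
using the *sample* standard deviation (n − 1 denominator), the
convention of `stats::sd`. PCA is computed on the standardised matrix
without further centring or scaling; loading-column signs are fixed so
the largest-magnitude entry of each column is positive, making fits
identical across eigensolvers. Either a fixed number of components
(`k`, default 4) or a cumulative-variance threshold is retained.
External species (e.g. fossil taxa) are *projected* into a fitted
space with the stored means, SDs, log flags and loadings — never
refitted — so they cannot distort the space they are measured in.

**Trait evolution.** Each retained axis evolves independently by
Brownian motion on the dated tree: the tip vector is multivariate
normal with mean `root_state` and covariance `sigma2 * C`, where
`C[i, j]` is the shared root-to-tip path length. `fit_bm()` uses the
closed-form GLS estimates: the root state is the GLS mean and
`sigma2` the maximum-likelihood rate (n denominator). Ancestral
states are the exact conditional means of the internal nodes given the
tips under the fitted model, computed from node–tip shared path
lengths; this is the multivariate-normal conditioning formula, not an
independent-contrasts approximation. Assumptions inherited from BM:
no trend, rate homogeneity in time and across clades, and axis
independence. Violations (e.g. early bursts) bias ancestral states
toward the GLS root and therefore *shrink* old slices toward a single
point; the slice truncation rule below keeps degenerate old slices out
of the homology stage.

**Time slices.** For slice age `a`, every branch whose parent is older
than `a` and whose child is at or younger than `a` contributes one
point, linearly interpolated along the branch (the BM bridge mean).
The slice at age 0 reproduces the extant tips exactly. The default
grid is 1-My intervals over the last 10 My: deeper slices hold too few
reconstructed lineages for loop detection, and reconstruction
uncertainty grows toward the root. If the grid reaches the root age,
it is truncated (with a warning) at the oldest slice holding at least
3 points.

**Persistent homology.** Each slice cloud passes through a
Vietoris–Rips filtration: a simplex (vertex, edge, triangle) enters at
the largest pairwise distance among its vertices. Boundary-matrix
reduction over GF(2), with the twist/clearing optimisation and a
union-find pass for dimension 0, yields the persistence diagram and a
representative cycle for every finite H1 class. Loops are the objects
of interest: a loop is a ring of occupied morphospace around an
unoccupied region, i.e. a gap. The implementation is in C++
(`src/rips.cpp`) because simplex counts grow cubically in the number
of points.

**Gap characterisation.** For a finite H1 bar with representative
cycle vertices `V`:

* persistence = death − birth (scale range over which the gap exists);
* centroid = mean of the cycle vertices' coordinates;
* size = mean distance from the centroid to the cycle vertices;
* sparsity = mean distance from the centroid to the `k` nearest cloud
  points, `k = ceiling(0.05 n)` (for 1378 points, `k = 69`). Low
  sparsity means the gap sits inside a densely occupied neighbourhood
  — the interesting case.

Gaps with persistence strictly greater than 0.4 PC units are
*notable*. Gaps in consecutive slices are linked when their centroids
lie within 1 PC unit, matched greedily nearest-first with one-to-one
assignment; chains of linked gaps are *series*, and a series' lifespan
is `age_max − age_min` (a gap seen in slices 3, 2 and 1 My has
lifespan 2 My — the span convention, so a single-slice series has
lifespan 0).

**Null model.** `generate_null()` simulates replicate tip datasets
from the *fitted* root and rate (nothing re-estimated per replicate)
and runs the byte-identical configuration through the same pipeline —
including re-reconstructing ancestors from the simulated tips, for
parity with the empirical run where ancestors are inferred, not
observed. The focal gap's (persistence, sparsity) pair is placed in
the pooled null gaps of the same slice age by a highest-density-region
quantile (section 3).

## 2. Defaults and their rationale

| Setting | Default | Rationale |
|---|---|---|
| `k` (PCs) | 4 | captures the bulk of variance in avian trait tables while keeping Rips complexes low-dimensional |
| `slice_interval` | 1 My | resolves series lifespans at the My scale used throughout |
| `max_age` | 10 My | older slices hold too few lineages and too much reconstruction shrinkage |
| Rips cap | enclosing radius | smallest cap that provably leaves no H1 class infinite, so every loop gets a finite persistence |
| `notable_threshold` | 0.4 (strict >) | retains roughly the top half-percent of gap persistences in BM-like clouds |
| `link_radius` | 1 PC unit | of the order of a notable gap's own size; larger radii chain unrelated gaps |
| `n_null` | 10 | enough for lifespan tallies; the KDE quantile flags itself below 30 pooled null gaps |
| `max_points` | 600 | triangle count at 600 points is ~3.6e7 — the desk-scale ceiling; `force = TRUE` overrides |
| sparsity rule | nearest 5% | scale-free in n; `k = ceiling(0.05 n)` |

Seeding: all randomness derives from one `master_seed` through a
deterministic hash of `(master_seed, replicate, axis)`, so each null
replicate and axis has its own reproducible stream, and changing the
master seed changes *only* the null ensemble, never the empirical
stages (which are deterministic).

## 3. Numerical conventions

* **Filtration order.** Simplices are sorted by (value, dimension,
  lexicographic vertex tuple). The tuple tie-break makes the reduction
  — and therefore representative cycles — independent of input row
  order up to point relabelling.
* **Zero-persistence bars** (birth = death, e.g. edges that connect
  already-connected components at their own scale) are dropped from
  diagrams but counted, so Euler characteristics can still be audited.
* **Enclosing-radius cap.** The default cap is
  `min_i max_j d(i, j)`: at that scale the complex is a cone over the
  minimising point and all H1 classes have died, so finiteness of
  every loop is guaranteed, at a fraction of the full-diameter cost.
* **Distance-matrix validation.** A square input must be symmetric
  with a zero diagonal and no negative entries, otherwise the call is
  rejected (pass `dist(points)` or the points themselves); a
  coordinate matrix that happens to be square would otherwise be
  silently misread.
* **KDE quantile.** Product-Gaussian kernel with Scott's bandwidth
  (`sd * n^(-1/6)` per axis, d = 2). The null density is evaluated at
  the null points *leave-one-out* (each point's own kernel mass
  removed); the focal point contributes no kernel of its own, so focal
  and null densities are exchangeable and the quantile
  `mean(f_null >= f_focal)` is calibrated — uniform under the null.
  With fewer than 30 null gaps the function falls back to flagged
  per-axis empirical ranks. HDR contour polygons are extracted at
  density thresholds equal to lower quantiles of the null density.
* **z-scores** use the sample SD (n − 1): three values (1, 2, 3)
  standardise to (−1, 0, 1).
* **Slice tolerance.** Branch–slice crossing tests use an absolute
  tolerance of `1e-9 * root_age` so tips of an ultrametric tree (whose
  computed ages are ~1e-16, not exactly 0) all appear in the age-0
  slice.
* **Config hash.** An FNV-1a hash of the canonical deparse of the
  configuration is stamped into every output file; empirical and null
  runs assert hash equality before being compared.

## 4. Synthetic generators

`make_circle_cloud()` (uniform angles, Gaussian radial noise) has a
known diagram — exactly one H1 class for small noise — and anchors the
homology tests. `make_pure_birth_tree()` rescales a Yule tree to an
exact depth. `make_planted_gap_dataset()` is the end-to-end testbed:
BM on a Yule tree, then a circular "forbidden" region of known centre
and radius enforced on the *tip* values only (ancestral
reconstructions then smooth over the hole, as they do for real data).
The untouched simulation is returned as a paired control.

Reference conditions (fixed once, before any detector runs): 150 tips,
10-My depth, `sigma2 = 1` per axis, 2 axes, hole centred at the BM
root, radius 1.5 (about 0.5 SD of the tip scores — the generator warns
above ~1 SD, where detection becomes trivial).

Two enforcement modes:

* **push** (default): offending tips are projected radially onto the
  hole boundary — displacement of species at the edge of a forbidden
  trait region. Always terminates.
* **reject**: the terminal-branch BM increment of each offending tip
  is re-drawn until it lands outside the hole. This preserves the BM
  marginal better, but when a tip's parent sits deep inside the hole
  at the end of a short branch, escape probabilities collapse; at the
  reference radius the retry budget is exhausted for a substantial
  minority of seeds, and the generator then stops with an error
  suggesting a smaller radius rather than silently changing the
  sampling scheme. This is why push is the default; reject remains
  available for small holes (it is exercised in the tests at radius
  0.8, where it never fails).

## 5. Problem sizes and runtime

The reduction handles a 150-point, 2-axis slice in about a second; a
full planted-gap pipeline (11 slices plus linking) takes 2–3 s, and a
10-replicate null comparison under a minute. The `max_points = 600`
guard keeps accidental large slices from consuming hours; overriding
it is a deliberate act (`force = TRUE`).

## 6. Known limitations

* **Paired planted-vs-control power is limited at the reference
  scale.** The location test is reliable: across 20 reference-scale
  seeds, the top modern gap's centroid falls within 2× the planted
  radius of the true centre every time. But "planted beats its paired
  control on top notable-gap persistence" holds in only ~70% of seeds:
  plain BM clouds of 150 phylogenetically correlated points naturally
  contain voids with persistence 0.8–1.4, comparable to a 1.5-radius
  hole (0.9–1.9), and for some seeds no tip falls inside the hole at
  all, making planted and control datasets identical. Larger holes or
  tip counts separate the distributions, at the cost of realism and
  runtime; users testing detector power should prefer the centroid
  criterion or raise the contrast deliberately.
* **Rate recovery tolerance.** With the ML estimator,
  `sigma2_hat ~ sigma2 * chisq(n − 1) / n` exactly, so at 200 tips the
  probability of landing within ±15% of the truth is 0.868 per
  replicate — an irreducible sampling property, not an implementation
  accuracy bound.
* **BM assumptions.** Trend, rate heterogeneity and correlated axes
  all bias ancestral slices; the package fits what it fits and makes
  no attempt to detect model violations.
* **Interpolated slices are means, not draws.** Slice points are BM
  bridge means, so ancient slices are smoother than true lineage
  values; gaps in old slices are conservative (under-detected).
* **Homology dimension.** Only H0/H1 are computed; void-like gaps
  (H2) in 3+ retained axes are out of scope.
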