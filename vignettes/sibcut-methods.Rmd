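---
title: "Methods: BCUT descriptor modeling of siRNA potency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCUT descriptor modeling of siRNA potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sibcut` treats a siRNA guide strand as a sequence of small molecules. Each
nucleotide monomer is reduced to twelve BCUT descriptors; a length-`L`
strand becomes the concatenation of its per-position vectors (252 numbers
for the canonical `L = 21`), and potency is regressed on that design with
partial least squares. The modeling assumptions are therefore:

* potency is (approximately) linear in the per-position physicochemical
  descriptors — position-specific additive contributions, no explicit
  pairwise sequence interactions;
* the 12 BCUT values capture the chemically relevant differences between
  monomers, so chemically modified nucleotides enter the model exactly like
  natural ones, through their own descriptor rows;
* dataset potencies are modeled on their native scale and direction
  (higher-is-better or lower-is-better is metadata the caller tracks, not a
  transformation the package applies).

## The BCUT engine

For a molecule with `n` heavy atoms the Burden matrix `B` has the atomic
property values on its diagonal; off-diagonal entries are `0.1 x` bond
order for bonded pairs (aromatic bonds count 1.5, and 0.01 is added when
either atom is terminal) and `0.001` for non-bonded pairs. Hydrogens are
never explicit atoms: their property contributions are folded onto the
attached heavy atom. Three diagonal weightings are used:

* **PEOE partial charges.** Gasteiger–Marsili iterative partial
  equalization with the published `(a, b, c)` electronegativity
  coefficients per element/hybridization class, six iterations, damping
  factor halving each round, charges seeded from formal charges and
  hydrogens reinstated as explicit iteration nodes. Lone-pair N/O atoms
  adjacent to a multiple bond (amide N, carboxyl O, aniline N) are given
  sp2 coefficients, matching standard conjugation perception. Per-molecule
  charge sums are conserved to the net formal charge by construction.
* **Wildman–Crippen logP and MR.** The published atomic-contribution table
  is applied through graph rules that mirror the original atom-type
  definitions in their priority order (C1–C27/CS, N1–N14/NS, O1–O12/OS, the
  four hydrogen classes, halogens, S, P). Atoms with no matching type fall
  back to the wildcard class with a warning. The implementation reproduces
  independent reference whole-molecule logP/MR sums on a 19-molecule
  battery and on the five nucleoside monomers; those frozen values are
  asserted in the test suite.

The four summaries per property are the type-7 quantiles of the sorted
eigenvalue spectrum at probabilities 0, 1/3, 2/3, 1 — i.e. the extreme
eigenvalues plus linearly interpolated third-order statistics at fractional
ranks `1 + (n-1)/3` and `1 + 2(n-1)/3`. This rule is continuous in `n` and
degenerates correctly to four copies of the single eigenvalue for a 1-atom
molecule; it also guarantees the `_0 <= _1 <= _2 <= _3` ordering invariant
within each property.

**Reference table versus computed values.** The packaged table for the
five natural nucleotides (`natural_descriptor_table()`) is the transcribed
reference fixture and is authoritative for natural-alphabet work. The
engine's own `bcut_vector()` output for the nucleoside structures satisfies
all structural invariants but does not numerically coincide with that
table: the original values were produced by a commercial package whose
Burden-matrix conventions (structural form, protonation, off-diagonal
scheme) are not published. We adopt the published Burden/BCUT convention
above, document it, and track the computed nucleoside vectors as regression
snapshots rather than forcing agreement. Monomer structures are drawn as
neutral nucleosides (no phosphate); the table builder is structure-agnostic
so users may supply any form they prefer.

Aromaticity is perceived from Kekulé input with a simplified Hückel rule
(5–7 rings, every member sp2-capable, π count `4n + 2`, exocyclic carbonyl
oxygens contributing zero); this reproduces standard perception for
benzenoid rings, azoles, furan and the amide-type nucleobase rings, which
is the chemistry this package encounters. Exotic ring systems (fused
polycycles beyond purine-like systems, charged rings) may be perceived
differently from full-featured toolkits.

## Encoding

Sequences are tokenized one character per position, or comma-separated when
the alphabet contains multi-character (modified) tokens. Encoding is a pure
table lookup: position `p` of the design carries columns
`nt{p}_BCUT_{property}_{k}` in fixed order, so labels round-trip position
and descriptor bijectively and the encoding of a concatenated sequence is
the concatenation of the encodings. Positions are reported 1-based, with
`nt20`/`nt21` the 3′ overhang in the canonical 21-mer layout.

## Rational train/test design

ART-2a operates on column-standardized descriptors (zero-variance columns
dropped) after L2 row normalization, because the three BCUT properties live
on different scales and the algorithm's similarity is a dot product.
Patterns are presented in a seeded random order; a pattern joins the
cluster of maximal centroid similarity when that similarity reaches the
vigilance, the centroid moving to the renormalized convex combination
`(1 - lr) c + lr x`, and founds a new cluster otherwise. Defaults:
learning rate 0.1, at most 20 epochs (stopping early when assignments
stabilize) — the algorithm's classical operating regime; both are
configurable, and all orderings are seeded so runs reproduce exactly.

`tune_vigilance()` bisects the vigilance in (0, 1) toward a requested
number of multimember clusters, stopping at the exact count or a bracket
of 1e-4 and returning the closest achieved count (ties toward the smaller
vigilance, misses reported with a warning). The count is not strictly
monotone in vigilance at the extremes — every pattern is a singleton as
vigilance approaches 1 — so the tuner tracks the best probe rather than
assuming monotonicity.

Test sets cover the multimember clusters: clusters are cycled in seeded
random order, one randomly drawn eligible member per cluster per pass,
until the requested size is reached; the global potency maximum and minimum
are never eligible, so extrapolation in the response is avoided by
construction. When the requested test size exceeds the eligible pool this
is an error for `design_split()`; the training-size scan, whose test sets
are intentionally huge at small fractions, covers clusters first and fills
the remainder by seeded random draw from non-extreme samples.

## PLS and evaluation

NIPALS PLS1 with centering and, by default, autoscaling of both predictors
and response. Autoscaling is a declared choice, not an inference about any
upstream work: BCUT magnitudes differ systematically across the three
properties, and the importance analysis reads coefficients in autoscaled
space so that rankings are scale-invariant; a center-only mode is kept for
sensitivity checks. With a single response the NIPALS inner iteration is
exact after one pass (the weight vector is the normalized covariance
direction), so no iterative tolerance is consumed; component extraction
stops early if the residual covariance norm or score variance falls below
1e-10. `"all"` components resolves to `min(N - 1, rank of the centered
design)` via a QR rank computation, which makes the full model coincide
with ordinary least squares on full-rank tall designs — one of the test
suite's oracles. Predictions flow through back-transformed original-space
coefficients; the latent-score path is kept internally and asserted equal
to 1e-8. Models serialize to JSON with 17 significant digits, which
round-trips doubles exactly.

Evaluation statistics are literal implementations of the product-moment
correlation, predictive `r² = 1 - RSS/TSS` (negative on poor held-out
predictions), and RMSE; they are tested against brute-force sum loops at
1e-10 on a thousand random pairs.

## Validation analyses

`multi_split_evaluation()` fits one model per split and reports per-split
and aggregate (mean/sd/max/min) statistics for both sets.
`pc_scan()` fits a grid of component counts (default `"all"`, 1..14) on a
fixed split. `training_size_scan()` re-splits per fraction with
`"all"`-component models. `y_scramble_test()` permutes the potencies once
per seed across the whole dataset *before* splitting — the potency extremes
move with the permutation — and reports the percent reduction of mean
correlation for train and test separately (the reduction is reported as NA
when the original mean correlation is non-positive, where a relative drop
is meaningless).

Relative importance of column `i` is `|b_i| / sum_j |b_j|` with `b` the
autoscaled-space coefficients, normalized per model, then averaged over
models; the per-position marginal averages each position's 12 columns and
the per-descriptor marginal averages each descriptor's `L` columns, both
renormalized to sum to one. Normalize-then-average-then-renormalize is a
declared resolution of an order-of-operations ambiguity; it keeps every
model's vote equal regardless of its coefficient scale.

## The synthetic benchmark generator

The generator exists so every pipeline stage is testable with known ground
truth. Potencies are always `y = X_std beta + N(0, noise_sd)` with the
encoded design standardized first, making `noise_sd` a fraction of
unit-variance descriptor effects; 0.3 is the default "moderate noise". Two
canned shapes mirror the two study regimes:

* **large** — 2431 i.i.d. natural 21-mers with a sparse signal on two
  descriptor columns at each of positions 1, 2, 7, 11, 19 (positions chosen
  among the empirically important guide-strand positions). Token
  frequencies are uniform, which real genome-derived sets are not.
* **small** — a 48-compound modification panel: two parent sequences and
  four modification sites (positions 1, 2, 7, 11), each toggling
  independently to a dedicated synthetic modified token, plus sparse
  nuisance modifications (probability 0.05 per remaining position) from a
  21-token synthetic modified alphabet. The signal sits on the `BCUT_SMR_3`
  column of the four sites, so the structure–potency relationship spans
  four latent binary directions plus the parent contrast. This emulates
  the decisive feature of real modified-siRNA panels — few parent
  sequences, systematic modification patterns, hence low effective
  dimensionality and natural multimember clusters — rather than their
  chemistry. An earlier i.i.d.-sequence variant of this shape was
  discarded: with independent random sequences the signal is spread over
  hundreds of effective dimensions and no 39-sample training set can
  recover it, which says something about i.i.d. designs, not about the
  pipeline.

Synthetic modified alphabets perturb natural descriptor rows with seeded
Gaussian noise (sd 0.15) and re-sort each property block so the eigenvalue
ordering invariant holds. What passing benchmarks show is that the pipeline
recovers planted linear structure at realistic sample shapes; they cannot
show that real siRNA potency *is* linear in BCUT descriptors, nor validate
the descriptors' chemical fidelity beyond the reference checks in the
engine tests.

## Problem sizes and runtime choices

The shipped analyses use the full large shape (2431 sequences, 10 rational
splits, all-component models), 30 splits at the small shape, 5 scramble
splits, and a 500-sequence importance study — sizes chosen to match the
study regimes while keeping a complete run in the low minutes on one core.
The ART-2a run on the large shape uses a fixed moderate vigilance (0.35)
rather than a tuned one: tuning requires a dozen clusterings and adds
nothing to analyses that only need a reasonable multimember cover.

## Known limitations

* The descriptor engine targets organic chemistry over H/C/N/O/P/S and
  halogens; other elements are a hard error for PEOE and a warned wildcard
  for Crippen types.
* Aromaticity perception is the simplified Hückel rule described above.
* Exact numeric agreement with descriptor tables produced by commercial
  software is out of scope; the packaged natural-nucleotide table is the
  bridge when reproducing published natural-siRNA work.
* Sense-strand effects, target-site accessibility, thermodynamic duplex
  features and applicability-domain filtering are outside the model.
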