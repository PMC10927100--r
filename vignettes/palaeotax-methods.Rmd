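---
title: "Methods: coherence testing of cultural taxonomic units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherence testing of cultural taxonomic units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeotax)
```

# The problem and the data model

Cultural taxonomy in the European Final Palaeolithic and earliest
Mesolithic rests on named archaeological cultures (NACs) that experts
group into a handful of higher-order macro-units. `palaeotax` treats the
coherence of those units as a measurable property of three data domains:
tri-state (present / absent / unknown) trait matrices for toolkit
composition (*Tools*, 24 traits in the reference schema) and technological
organisation (*Technology*, 52 traits), and closed 2D armature outlines
with site, NAC, and time-slice metadata. Observations sit in one of four
millennial time-slices (I–IV, 15–11 ka cal BP); an observation spanning
several slices is duplicated into each of them before any slice-aware
analysis (`expand_timeslices()`).

The unknown trait state is represented as an explicit `NA`, never as a
numeric sentinel. This is a hard invariant: distance computations must
either handle unknowns by pairwise deletion or fail loudly, and nothing can
silently average over them.

# Outline morphometrics

Outlines pass through a fixed preprocessing chain:

1. **Smoothing** — a cyclic 3-point moving average, 5 passes by default.
   The pass count is configurable; 5 passes of the minimal window suppress
   digitization jitter while preserving corner geometry at the scale of the
   500-point resampling that follows.
2. **Normalization** (`orient_outline()`) — translation to the centroid,
   scaling to unit centroid size, counter-clockwise traversal, and cyclic
   re-indexing so the first vertex is the distal tip. The tip is the vertex
   farthest from the centroid along the principal elongation axis. When the
   two ends of that axis are within 10% of each other, the pointier end
   (smaller RMS off-axis width within a 15% arc window) wins. This
   tie-break matters: for near-symmetric pieces the plain farthest-point
   rule flips between the ends under digitization noise, which splits a
   single morphological class into two artificial start-point modes and
   wrecks every downstream within-group statistic. Remaining ties break to
   the lowest vertex index, keeping the rule deterministic.
3. **Semi-landmarking** — resampling to exactly 500 points equally spaced
   in arc length, with point 1 anchored at the tip.

Elliptic Fourier analysis follows the standard chord-length
parameterization: per harmonic *n* the quadruple (a_n, b_n, c_n, d_n), plus
offsets. Harmonic power is P_n = (a_n² + b_n² + c_n² + d_n²)/2 and the
retained harmonic count is the smallest N whose mean cumulative power share
reaches 99.9% across the outline set. No first-harmonic ("first ellipse")
normalization is applied by default: it would rotate away the deliberately
fixed tip landmark. Invariance to translation, scale, and traversal
direction is carried entirely by the preprocessing chain.

Two numerical facts about this parameterization are worth knowing. First,
an eccentric ellipse sampled from its angular parameter does *not* reduce
to a single harmonic under chord-length parameterization — the
reparameterization puts a fraction of the power (≈0.2% at axis ratio 1.5)
into the odd harmonics. This is correct behaviour, and it means the "one
harmonic describes an ellipse" intuition holds exactly only for circles
and approximately for mild ellipses. Second, forward analysis after
truncated reconstruction is exactly idempotent only for band-limited
curves; on noisy outlines a ~1% coefficient residual persists, because
truncation alters the curve's arc-length parameterization.

The PCA shape space (`pca_shapespace()`) centers but never rescales the
coefficient columns (they share units; scaling would distort the power
ordering) and retains all components up to numerical rank, so Euclidean
distances in PC space equal distances between centered coefficient rows to
machine precision. The component count is whatever the data's rank yields;
it is reported, never asserted.

# Dissimilarities

* **Gower** on tri-state traits: mean absolute difference over the traits
  known in both rows. Shared absence counts as agreement (symmetric
  treatment; an asymmetric Jaccard-like variant is available but
  non-default). A pair with no jointly known trait is an error naming the
  pair — no imputation. On complete binary data this reduces to
  Manhattan/ncol, which the test suite cross-checks against both a
  brute-force oracle and `cluster::daisy()`.
* **Shape**: Euclidean over all PC scores.
* **Geography**: haversine great-circle distance on the mean-radius sphere
  (R = 6371.0088 km), either between sites or between NAC regional
  centroids, the latter computed as arithmetic means of site coordinates in
  decimal degrees — adequate at the continental extent involved and
  faithful to "mean site coordinates".
* **Time**: |rank difference| of single-slice observations (I..IV mapped to
  1..4). Multi-slice observations are excluded from time analyses, not
  expanded.

# The SES coherence test

For each (domain, macro-unit) the observed statistic is the mean pairwise
distance among the unit's members; the null is generated by drawing
`n_resamples` same-size groups uniformly without replacement from the pool
(members stay eligible), and

SES = (Metric_obs − mean(Metric_null)) / sd(Metric_null).

The sampling unit is the *entity* (NAC row or outline), not the pair:
drawing entities and taking their induced pairs is the only reading under
which "groups of size n" keeps its meaning. A pair-resampling variant is
exposed (`unit = "pairs"`) for sensitivity analysis without any claim of
equivalence. Defaults are 10,000 resamples for trait domains and 100,000
for outlines. Significance uses the fixed ±2 rule; an empirical two-sided
quantile p-value is reported alongside for transparency. A constant
distance matrix has a zero-variance null and raises an explicit
degenerate-null error rather than returning an infinite SES. Groups with
fewer than two members in a domain are skipped with a warning, never
silently dropped.

Calibration: under an exchangeable null (iid Uniform dissimilarities) the
empirical |SES| ≥ 2 rate sits at ~5% and the SES mean within ±0.1 of zero
(the acceptance suite measures 1000 random groups of 10 from a 100-entity
pool at 1000 resamples each). One caveat the tests make explicit: when the
pool itself contains strong clusters, randomly re-labelled groups overlap
those clusters hypergeometrically, so the exceedance rate under label
permutation is slightly above the nominal 5% (measured ≈8.6% for the
default synthetic pool). That residual is a property of the study design,
not of the statistic.

# Trees, bootstrap, tanglegrams

Ward clustering uses the `ward.D2` convention (squared-dissimilarity
Lance–Williams update applied to unsquared input), with `ward.D` behind a
flag. Bootstrap support resamples *variable columns* (traits, or PC
scores) with replacement — character support in the phylogenetic sense;
rows are never resampled. Support of an internal branch is the percentage
of 1000 replicates containing the same leaf clade; branches below 50% are
collapsed into polytomies. Outline trees are built on a stratified
subsample of two outlines per NAC (uniform without replacement, keeping
whatever a rarer NAC has).

`tanglegram_compare()` reports the non-trivial clades shared by two trees
over the same leaves and an entanglement score in [0, 1]: after one greedy
bottom-up pass that orders each subtree of the second tree by the mean
reference position of its leaves, the L1 distance between the two leaf
rank orders, normalized by its maximum ⌊n²/2⌋. The score is
package-defined (the underlying comparison is usually done visually) and
documented as such; identical trees score 0.

# Space, time, disparity, CART

Mantel tests (Pearson or Spearman, one-tailed permutation p with add-one
correction) and Mantel correlograms are delegated to vegan, the standard
toolchain for these tests. Correlogram classes are equal-width bins with
the class count set by Sturges' rule on the number of distance pairs; the
first break is nudged below the minimum so the classes are exhaustive;
p-values are Hochberg-adjusted across classes. Per-class tests follow
vegan's sign-directional one-tailed convention. Classes with fewer than 10
pairs are reported but flagged untestable. The default permutation count is
999 everywhere — a declared package choice.

Disparity of a time-slice is the sum of per-axis score variances
(denominator n−1 — the unbiased within-slice estimate; the equivalent
trace-of-covariance form makes rotation invariance explicit), with a
percentile bootstrap CI from resampling outlines within the slice, and
pairwise slice contrasts by a permutation test on |D_A − D_B| with add-one
correction. Rarefaction to a common n is available as an option where
sample sizes differ strongly.

CART (`fit_cart()`) maps the analysis onto `rpart`: Gini splits, growth at
`cp = 0` (a negative cp corrupts rpart's internal cross-validation — found
the hard way on a perfectly separable fixture), pruning to the subtree with
minimum cross-validated error, rows with unknown states retained and routed
by surrogates falling back to the majority branch. This is a declared
mapping of the "partial data" / "minimum error" options of the original
proprietary tool, not a claim of bit-compatibility. Variable importance is
rpart's total Gini decrease including surrogate credit, normalized to
sum 1.

# The synthetic generator: what it emulates, and what not

`simulate_dataset()` plants, under one seed, every signal the pipeline is
supposed to detect:

* **Macro-unit trait structure** — each unit has a trait archetype; a cell
  is the archetype value flipped with probability ε (default 0.05), then
  set unknown with probability m (default 0.1). Archetype strength p_in
  (default 0.9) is the probability a trait's archetype state is
  unit-specific rather than inherited from a global base vector. Two NACs
  of 86 stay unassigned; unit sizes follow the reference study's relative
  proportions. One technology trait (*en éperon* platform preparation) is
  planted as a fully reliable Magdalenian hallmark, exempt from noise.
* **Spatial autocorrelation** — the 16 regions sit on a grid with spacing
  at least `spatial_decay_km` (default 300 km); macro-units occupy
  contiguous region blocks, and sites scatter around their region centroid
  at ~1/6 of that scale. Trait similarity therefore decays with distance,
  which the Mantel correlogram recovers as a significantly positive
  first-class correlation.
* **Chronological shape signal** — six armature outline families are
  authored as close variants of one elongated pointed form (between-family
  template variance ≈ 0.005 in coefficient units), each with a sharply
  tapering tip and a slowly tapering base so the orientation rule is stable
  under noise. Within-family dispersion follows the per-slice schedule σ =
  (0.05, 0.05, 0.10, 0.14), chosen inside the measured flip-free stability
  region of every family; the first-harmonic noise multiplier is damped to
  0.25 because real within-class variation lives in proportions, not gross
  ellipse shape. A deterministic mean-shape drift common to all families
  (harmonics ≥ 2 only) separates the slices in shape space, planting a
  positive Spearman correlation between shape distance and time distance
  without touching any slice's internal variance.
* **Composition balance** — every macro-unit contributes the same number of
  outlines to every time-slice (round-robin over its NACs present in that
  slice), and unassigned NACs contribute none. Without this, per-slice
  disparity is dominated by which families happen to be sampled into a
  slice rather than by the dispersion schedule, and the planted
  disparity-through-time pattern (stable I–II, increase into III, again
  into IV) drowns in composition noise.

What the generator does **not** emulate: research-tradition and analyst
biases, the real dataset's strongly uneven per-NAC outline sample sizes,
non-contiguous cultural geographies, trait correlations within archetypes,
and any quantitative effect size of the real data. Passing tests therefore
demonstrate that the pipeline detects structure of the planted kind at the
planted magnitude — they say nothing about whether the real archaeological
record contains such structure, and the generator's effect sizes are
calibration targets, not estimates.

# Numerical choices and degenerate inputs

* Distance matrices are validated to symmetry 1e−12 and exactly zero
  diagonal; Gower is bounded in [0, 1].
* Agglomeration ties break to the lowest-index pair (hclust's convention),
  making tree construction deterministic.
* All randomized stages accept a `seed` and run inside an isolated RNG
  scope (`withr::with_seed`), so a fixed seed reproduces results to the
  bit without clobbering the caller's RNG. The generator derives
  per-entity sub-seeds by hashing the base seed with the entity id, so
  reproducibility does not depend on generation order.
* Degenerate inputs fail loudly: empty trait files, all-coincident
  vertices, zero-perimeter outlines, constant distance matrices,
  zero-variance Mantel triangles, sub-two-member groups, outline draws
  that stay degenerate past the retry cap.
* Site quality is a rubric-bounded integer sum (default rubric: chronology
  2, stratigraphy 2, assemblage integrity/coherence 1, investigation
  recency 1 — maxima summing to 6, matching the four named criteria); the
  breakdown is configurable because only the total's range is fixed.

# Problem sizes in the shipped tests

The test suite exercises the full default dataset (86 NACs, ~530 outlines
at 500 semi-landmarks) where the contract concerns it, and reduced sizes
elsewhere: SES calibration at 1000 groups × 1000 resamples, bootstrap
consensus at 40–100 replicates, permutation tests at 99–499 permutations,
and the end-to-end pipeline at 30 NACs with 120 semi-landmarks. These
sizes were chosen so the whole suite documents the method's behaviour in
under a minute; the package defaults remain at the full study-scale values
(1000 bootstrap replicates, 10,000/100,000 SES resamples).

# Known limitations

* The entanglement score and the correlogram tail convention are package
  choices where the field's practice is visual or unstated.
* Greedy CART cannot express a zero-marginal-gain interaction (exact XOR);
  the tests document this with a near-XOR fixture.
* Centroid averaging in degrees ignores sphericity; do not use it near the
  poles or across the antimeridian.
* The Gower implementation targets binary-with-unknown traits; ordinal or
  quantitative traits would need range normalization it does not do.
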