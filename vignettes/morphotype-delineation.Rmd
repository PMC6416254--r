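---
title: "Delineating scale morphotypes from length variables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating scale morphotypes from length variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalemorph)
```

## The problem

Early osteichthyan fishes were covered by hundreds of rhombic ganoid
scales whose shape varies systematically over the body. When such scales
are found disarticulated, assigning them to body regions requires first
sorting them into recurrent shape classes — morphotypes — and then tying
each morphotype to the region where articulated material shows it. This
package implements the quantitative half of that workflow for crown-view
scale measurements:

1. derive length variables from an 11-landmark configuration of each scale;
2. prune variables that are collinear with easier-to-measure ones;
3. cluster the scales (squared Euclidean distance, between-groups linkage);
4. validate and refine the grouping with canonical variate analysis (CVA);
5. summarise each group and map morphotypes onto a 4-belt / 16-area
   squamation model.

The flank scales analysed here are unusual among early osteichthyans in
being much *higher* than long: reference height/length ratios run from
about 1.1 (low ventral scales) to 4.75 (tall anterior flank scales).

## Length variables and their landmark definitions

Eleven crown-view landmarks are used: peg tip (1), anterodorsal-process
tip (2), dorsal-margin midpoint (3), anterior-margin/process intersection
(4), dorsal/posterior crown corner (5), its anterior-margin projection (6),
posterior/ventral crown corner (7), its base-margin projection (8), and the
posterior base corners (9, 10) plus the keel/ventral-base intersection (11).

The landmark definitions force three of the lengths — scale length
`L5 = d(5,6)`, scale height `L6 = d(5,7)`, and the base's posterior margin
`L8 = d(9,10)` — and the package completes the set with the simplest
faithful constructions: process length `L3 = d(2,4)`; peg length `L1` as
the perpendicular distance of landmark 1 beyond the dorsal margin (the
line through landmarks 4 and 5, with landmark 7 marking the interior
side — this makes `L1` invariant under reflection); and the
anteroposterior extent `L4` as the projection range of landmarks 2–7 on
the unit axis `u = unit(P5 − P6)`. An isolated scale carries no body
frame, so the scale's own length axis stands in for the longitudinal body
axis. Whether peg length should instead be measured along the peg axis is
not decidable from the material; the perpendicular convention is the
default and the landmark/length mapping is deliberately kept in one place
(`compute_length_variables`) so alternative conventions are easy to swap.

Two variables are special. The concealed-field length `L7` has no defining
landmark and is treated as a directly measured optional input. The keel
length `L2` is proxied by `d(1,11)`. Both are pruned by variable selection
before clustering (they track `L5` and `L6` respectively), so neither
approximation ever reaches the analysis.

## Variable pruning

Pairwise Pearson correlations are computed on raw millimetre values — all
eight variables share a dimension, so no standardization is applied — and
variables with `|r| >= 0.90` are linked; connected components of that graph
form clusters of mutually dependent variables; within each cluster the
variable earliest in a preference order (`L6, L5, L1, L3, L4, L2, L7, L8`,
encoding which length is easiest to measure on worn fossils) is kept. The
0.90 cutoff is a package default: the source analysis reports only that
dependence was "strong", and 0.90 reproduces the described grouping
({L2, L6, L8} represented by L6, {L5, L7} by L5) on data with that
structure while leaving the rest untouched. Transitive grouping is
intentional and documented: three variables can share one representative
even if one pairwise link is marginal. Raising the threshold can only
grow the kept set (asserted as a property test).

## Clustering

The Q-type (case-wise) agglomerative clustering is implemented from
scratch: pairwise squared Euclidean distances on the selected variables,
between-groups linkage (the inter-cluster distance is the mean over all
cross-pairs of point distances), maintained incrementally with the exact
Lance–Williams update for average linkage. Ties in the minimum linkage are
broken by the lexicographically smallest member identifiers; determinism
matters more than the particular choice, and it makes partitions invariant
to row order. Average linkage is reducible, so merge heights must be
non-decreasing; the implementation asserts this on every run. Correctness
is guarded two ways in the tests: an O(n³) brute-force oracle that
recomputes every cross-pair mean at every step (200 random instances,
n ≤ 12), and `stats::hclust(method = "average")` on the squared distance
matrix at larger n.

Cutting at `k` undoes the last `k − 1` merges; groups are renumbered by
descending size, then by smallest member identifier. `compare_k` reports
group sizes, within-group dispersion and the mean Euclidean silhouette
for each candidate `k` but never chooses: in the source workflow the
choice of 8 groups over 7 or 9 was made against the articulated fossils,
a judgement no internal index can reproduce.

## Canonical variate analysis and refinement

CVA solves the generalized eigenproblem of `W⁻¹B` (between-group scatter
`B`, pooled within-group scatter `W`) via symmetric whitening with the
inverse square root of the pooled within-group covariance, which is
numerically stabler than inverting `W` directly; the dense solve-and-
eigendecompose route survives as the test oracle. Axes are scaled to unit
pooled within-group variance; at most `min(g − 1, p)` axes are retained.
Classification is by Mahalanobis distance to group means under the pooled
covariance with equal priors (linear discrimination), ties to the lowest
group id. Accuracy is resubstitution — the workflow validates the labels
of the very scales that were clustered, and no claim of out-of-sample
performance is intended; cross-validation would answer a different
question. Classification is invariant under any invertible affine
transform of the variables, which the tests exercise directly.

A single-member group is legitimate here (one morphotype is known from
one scale): it contributes a mean but no within-group scatter. A ridge
option `W + λ·diag(W)` exists for degenerate inputs (a variable with zero
within-group scatter falls back to a unit ridge so the rescue always
works); the default is `λ = 0` and the synthetic study conditions never
need it.

Refinement mirrors the source workflow's single adjustment pass: fit,
classify, move every misclassified scale to its predicted group, refit.
`max_rounds = 1` is the default; the loop also stops at a fixpoint. If a
reassignment empties a group, the group is retired with a warning and the
group count drops — the alternative (forbidding the move) would leave a
label the model itself rejects.

## Group summaries and morphotype matching

Summaries use the population SD (divisor *n*): the reference table prints
SD 0.00 for its single-scale morphotype, which is undefined under the
n − 1 convention. Ratio statistics are means of per-scale ratios, never
ratios of group means; the two differ (reference morphotype 1 prints
height/length 4.75 while its mean height over mean length is 4.71), and
only the per-scale convention reproduces the printed columns.

Cluster groups are anonymous, so they are matched to the eight reference
morphotypes by the one-to-one assignment minimizing total Euclidean
distance between the feature vectors (L5 mean, L6 mean, L6/L5 mean). The
package searches exactly by depth-first branch and bound (group counts
are ≤ 10; the test oracle enumerates all permutations), and reports the
total assignment cost so a structurally poor match is visible rather than
silent. Where the descriptive text and the reference table disagree on a
ratio (morphotype 6: 2.34 vs 2.73; morphotype 11: 1.04 vs 1.11), the
table values are used and the text readings carried as metadata — the
discrepancy is in the source material and is not "fixed" here.

## The synthetic generator

`default_reference_spec()` encodes the study conditions: 8 clusters
with sizes 23/64/49/37/27/15/10/1 (226 scales; the singleton is
morphotype 12), L5 and L6 means/SDs straight from the reference
parameters, and L1, L3 means recovered from the ratio columns
(`mean(L1) = mean(L1/L6) · mean(L6)`) with first-order SD propagation.
`L4` has no published statistics and defaults to L5's mean and SD — both
measure the anteroposterior extent of a rhombic scale. Draws are
independent normals truncated at zero (negative draws clamp to 0; at the
reference mean/SD ratios of 4 and above this is vanishingly rare).

What the generator does *not* emulate: inter-variable covariance within a
morphotype (only marginal SDs are published; a covariance hook exists on
the spec for harder tests), measurement error structure, allometric
gradients within a body region, and the possibility that the real
morphotypes are non-Gaussian or overlapping in ways the table's moments
do not capture. Passing the recovery tests therefore shows the pipeline
recovers clusters *of the published geometry*, not that the original
material would cluster identically.

Under these conditions, k = 8 clustering recovers the multi-member
clusters with median adjusted Rand index above 0.7 across 20 replicate
simulations (the singleton is excluded from the ARI, as a single scale
cannot meaningfully be "recovered"), and one CVA refinement round does
not lower resubstitution accuracy in at least 18 of 20 noisy-label
replicates. The nearest reference clusters (morphotypes 10 and 11, and
1 vs 2) overlap at roughly two pooled SDs, which is what keeps the ARI
around 0.7–0.8 rather than near 1: the published groups are genuinely
adjacent in measurement space.

`generate_landmarks` inverts the length computation: it builds an
11-landmark rhombic outline whose derived L5, L6, L1, L3 equal requested
values exactly, then jitters coordinates at a stated noise level. This
gives the morphometry tests a round-trip oracle that is independent of
the forward code path.

## Numerical choices, in one place

* Clustering tie-break: lexicographically smallest member ids; partition
  labels renumbered by size then smallest member id.
* Merge-height monotonicity asserted with a 1e-8 relative tolerance
  (floating-point guard on an exact mathematical property).
* CVA whitening rejects a pooled covariance whose smallest eigenvalue is
  below 1e-10 of the largest, with the ridge option as the advised rescue.
* Mahalanobis ties: lowest group id.
* Assignment search: exact branch and bound with row-minimum lower bounds.
* Degenerate inputs fail loudly and early: duplicate identifiers,
  non-finite or negative lengths, zero-variance variables, L5 or L6 equal
  to zero in ratios, landmark configurations with coincident margin
  landmarks.

## Problem sizes in the test-suite and analysis scripts

The tests run the full 226-scale pipeline, 20 replicate simulations for
the recovery and refinement properties, 200 random instances (n ≤ 12)
against the brute-force clustering oracle, and a few dozen randomized
geometry and CVA cases; the whole suite completes in well under a minute.
These sizes were chosen to match the study's own scale — 226 scales is
the real problem size, not a reduction.

## Known limitations

* The landmark-to-length mapping for L1–L4 is a reconstruction from the
  landmark definitions, not a published formula; it is configurable at
  one site and validated only by internal consistency.
* Tier-two replication against the original supplementary measurement
  table requires that table; the pipeline accepts it via
  `read_measurement_table`'s schema mapping whenever it is available.
* The squamation map is a data structure (areas, belts, morphotype
  assignments, bounds text), not a spatial reconstruction; it supports
  lookup and reporting, not rendering.
* Matching anonymous groups to morphotypes by nearest means can be
  unstable when two reference morphotypes are close; the reported total
  cost and per-group costs are the guard against over-reading such a
  match.
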