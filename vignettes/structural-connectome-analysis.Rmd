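---
title: "FA-weighted structural connectome analysis with fanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FA-weighted structural connectome analysis with fanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanet)
```

## The analysis fanet implements

Diffusion-MRI connectome studies of cognitive decline follow a now-standard
recipe: parcellate the brain into N regions (typically the 90 cerebral AAL
regions), track white-matter streamlines deterministically through the
voxel-wise principal diffusion directions, connect two regions when enough
streamlines run between them, weight each connection by the mean fractional
anisotropy (FA) along the connecting fibers, and then compare the resulting
weighted graphs between clinical groups — globally (efficiency, path
length, clustering, small-worldness), regionally (nodal efficiency,
betweenness, hubs), and edge-wise (the network-based statistic, NBS).

`fanet` implements that full analysis layer as reusable, tested R
functions. Because raw diffusion MRI is rarely shareable, the package also
contains a first-class synthetic cohort generator that reproduces the
*statistical structure* such studies assume — three groups with a graded
global-efficiency deficit, an impaired subnetwork in the most affected
group, and cognitive scores coupled to network efficiency — so every stage
can be validated end to end against a known ground truth.

## Network construction

### Streamline tracking

`track_fact()` implements deterministic fiber-assignment-by-continuous-
tracking on a voxel orientation field (per-voxel FA, principal direction,
parcel label). The tracking rules are the classical ones:

* every voxel with FA ≥ 0.2 seeds one bidirectional streamline;
* propagation hops voxel-to-voxel along the local principal direction;
* a track terminates on leaving the grid, on reaching a voxel with
  FA < 0.2, or when the direction turns by more than 45°.

Two conventions had to be fixed where the classical description is silent,
and both are deliberately the simplest checkable choice:

* **Voxel-hop stepping.** The next voxel is the neighbour given by
  component-wise rounding of the unit direction (dominant axis when the
  rounding is degenerate), rather than sub-voxel trilinear interpolation.
  This keeps every worked example exactly reproducible by hand.
* **Bidirectional launch with sign alignment.** Each seed is tracked along
  `+d` and `−d` and the halves concatenated; at every step the next voxel's
  direction is sign-flipped to align with the current travel direction
  before the angle test, so the turning angle is well defined (≤ 90°).
  A 90° local turn therefore always terminates the track.

Collinear seeds produce duplicate trajectories and these count as distinct
fibers: fiber *count*, not trajectory uniqueness, is what the edge rule
below consumes.

### From streamlines to a matrix

`build_matrix()` applies the two standard filters: an edge exists only if
at least `min_fibers = 3` streamlines connect the two regions (suppressing
spurious connections), and its weight is the mean FA over *all voxels of
all connecting streamlines*. Pooling over voxels (rather than averaging
per-streamline means) weights longer fibers proportionally to the tissue
they traverse; for equal-length streamlines the two conventions coincide.
Streamlines touching background (label 0) or looping within one region are
discarded. The output is a symmetric, zero-diagonal matrix with weights in
`[0, 1]` — the package's central object.

## Graph metrics

All path-based metrics use the distance mapping `d = 1/w`: a stronger
(higher-FA) connection is a shorter route. With weights in `(0, 1]`,
distances are ≥ 1. The conventions, fixed once and validated against an
independent brute-force oracle in the test suite, are:

* **Characteristic path length Lp** — mean shortest-path distance over
  *connected* ordered pairs. Disconnected pairs are excluded from the
  average rather than imputed, so Lp stays finite on fragmented
  thresholded networks.
* **Global efficiency Eglob** — mean of `1/d` over all ordered pairs,
  disconnected pairs contributing 0 (Latora–Marchiori). This is the
  complementary treatment of disconnection: fragmentation lowers Eglob.
* **Clustering Cp** — Onnela geometric-mean weighted clustering, with
  weights normalized by the matrix maximum. A triangle of equal weights
  has coefficient 1 regardless of the common weight, so Cp measures
  topology-weighted closure, not overall strength.
* **Local efficiency Eloc** — mean over nodes of the global efficiency of
  the neighbour-induced weighted subgraph; nodes with fewer than two
  neighbours contribute 0.
* **Nodal efficiency** — mean inverse distance from a node to all others;
  **betweenness** — fraction-weighted shortest-path counts under the same
  `1/w` distances, each unordered endpoint pair counted once.

These are the dominant conventions in weighted-connectome toolboxes, but
they are conventions: toolboxes differ in normalization factors, so
absolute metric values are comparable only within a convention. The
package therefore validates *internal* correctness (oracle equivalence,
scaling laws, monotonicity under edge deletion) rather than any published
absolute value.

### Sparsity thresholding

`threshold_by_sparsity()` retains the `K = round(s·N(N−1)/2)` strongest
edges (half-away-from-zero rounding; weight ties broken by ascending
`(i, j)` order so results are deterministic) and keeps the surviving
weights. Metrics are computed over the sparsity grid 0.10–0.15 in steps of
0.01 — the range in which FA-weighted structural networks show stable
small-world organization — and each curve is summarized by its trapezoidal
area under the curve (AUC), removing the arbitrariness of any single
threshold. The wider screening range up to 0.30 is available through
`sparsity_grid()`.

### Small-world normalization

`random_reference()` builds degree-preserving surrogates by double-edge
swaps of the binarized topology (10 attempted swaps per edge) and then
permutes the original weight multiset onto the rewired edges. This
preserves each node's binary degree exactly and the global weight
distribution exactly, destroying only the topology–weight organization.
Then γ = Cp/⟨Cp_rand⟩, λ = Lp/⟨Lp_rand⟩ and σ = γ/λ; σ > 1 is the
small-world criterion. Reference-quality runs use 1000 surrogates; the
package defaults to 100 in screening contexts, which bounds the surrogate-
mean error well below the γ − 1 margins observed on realistic networks.
For topologies that swaps cannot change (complete graphs, stars) the
surrogates equal the original and γ = λ = σ = 1 exactly.

### Hubs

A node is a hub when its betweenness is at least the network mean plus one
sample SD (`identify_hubs()`). When all betweenness values are equal the
SD is 0 and every node is flagged — degenerate but well defined, and
documented rather than special-cased. Group-level hubs are computed on the
group-mean connectivity matrix (thresholded at the top of the sparsity
range); per-subject hub sets can equally be derived by applying the rule
to each subject's betweenness vector.

## The network-based statistic

`nbs_test()` implements the NBS exactly as the field uses it:

1. an edge-wise statistic over all edges present in ≥ 50% of subjects
   (one-way ANOVA F for the omnibus contrast, pooled-variance two-tailed t
   for pairwise contrasts);
2. a primary component-forming threshold, uncorrected `p < 0.01`;
3. connected components of the suprathreshold edges, sized in edge counts;
4. an empirical null of the *maximal* component size under full random
   relabelling of subjects (5000 permutations by default);
5. a component-level corrected p-value: the proportion of permutations
   whose maximal component reaches the observed size.

Two numerical choices deserve note. The exceedance rule defaults to
`≥ M` with add-one smoothing, `(1 + #{max ≥ M})/(n_perm + 1)`, which
guarantees valid p-values bounded below by `1/(n_perm+1)` and never
exactly zero; the strict `> M` proportion is available via
`exceed_rule = "greater"`. And permutations compare the statistic against
the critical value equivalent to the primary threshold (e.g.
`|t| > qt(1 − p/2, df)`), which is algebraically identical to thresholding
permuted p-values but avoids a million incomplete-beta evaluations.
Edge-weight residualization on covariates before testing is supported but
off by default, mirroring common practice of adjusting the global/nodal
models but not the edge-wise NBS model.

## Group statistics

`ancova_group_effect()` tests the group factor by extra-sum-of-squares F
against the covariate-only model (age and 0/1-coded sex by default). With
uninformative covariates this is *exactly* the one-way ANOVA F — a
property the tests assert. Post-hoc pairwise contrasts come from the same
adjusted linear model and are gatekept on the omnibus p < 0.05, as in the
standard workflow (a non-gatekept mode exists for power studies);
correction is Bonferroni or Benjamini–Hochberg FDR. For nodal metrics, FDR
is applied across the 90 regions within each metric family, separately per
contrast — the most common convention where the literature leaves the
scope unstated. Brain–behaviour relationships use Spearman rank
correlation with average-rank ties and the asymptotic t approximation,
reported uncorrected as is conventional for these exploratory
correlations.

## The synthetic cohort model

`generate_cohort()` emulates the study design the analysis expects: three
groups (HC, NC, MCI) of 30 subjects, 90 regions.

* **Template topology.** One shared random geometric-modular graph: nodes
  get uniform 3-D coordinates, connection probability decays
  exponentially with distance (length scale 0.3 in unit-cube units) and
  doubles within one of four spatial modules, scaled to an expected
  density of 0.25. Distance dependence plus modularity produces the high
  clustering and short paths (σ > 1) of real connectomes, which an
  Erdős–Rényi graph would not.
* **Edge weights.** FA-like: mean 0.45, SD 0.10, mildly decreasing with
  edge length (short-range tracts are stronger), clipped to a plausible
  FA range. The distance–weight coupling keeps sparsity-thresholded
  networks spatially coherent, as in real data.
* **Group effect.** Multiplicative attenuation of all edge weights by
  0.93 per group step (HC → NC → MCI). Attenuation (rather than edge
  deletion) lowers Eglob and raises Lp smoothly without discontinuous
  density changes, matching the direction of reported group differences.
* **Subject variability.** A per-subject lognormal global scale
  (sd(log) = 0.03, giving ≈ 3% between-subject efficiency variability,
  typical of such cohorts) times per-edge lognormal noise
  (sd(log) = 0.10).
* **Planted subnetwork.** An 8-edge connected tree (9 nodes) grown along
  template edges — preferring strong edges so a 0.2 FA deficit reduces
  rather than deletes tracts — attenuated only in MCI subjects. This is
  the ground truth against which NBS recovery is scored.
* **Cognition.** DST-forward, TMT-A and TMT-B scores are affine in the
  subject's true (unthresholded) global efficiency plus noise, signed so
  higher efficiency means better DST and *faster* (lower) TMT times; the
  standardized slope is 1 with unit noise, a strong but not deterministic
  coupling.
* **Covariates.** Age, sex and education are drawn independently of group
  (a matched design), so covariate adjustment is exercised without
  confounding.

One master seed drives a template stream and per-subject substreams
derived by counter offset, so cohorts are bit-reproducible and independent
of generation order, and generation does not disturb the caller's RNG.

What the generator does *not* emulate: scanner physics, motion artefacts,
tract-length biases of real tractography, spatially heterogeneous disease
effects, or covariate–group confounding. Passing the recovery tests
therefore demonstrates that the statistical machinery is correct and
calibrated — not that it would detect effects of this size in real MRI.

## Validation strategy and problem sizes

The test suite validates each layer at sizes chosen for a desk-scale run:

* metric implementations against a brute-force Floyd–Warshall /
  path-enumeration oracle on 100 random weighted graphs (N ≤ 12), to
  1e-9;
* NBS type-I error on 200 null cohorts (two groups × 15 subjects, 500
  permutations): the rejection rate at corrected p < 0.05 must lie in
  [0.01, 0.10];
* NBS power on 50 cohorts with only the planted 8-edge deficit
  (delta = 0.2, 30 subjects/group): a significant component overlapping
  the planted edges with Jaccard ≥ 0.5 in ≥ 90% of replicates;
* ANCOVA recovery of the graded efficiency deficit on 50 cohorts (and
  ≈ 5% null rejection on 50 null cohorts);
* small-worldness σ > 1 at every sparsity in 0.10–0.15 for ≥ 95% of
  subjects of a default cohort, with 100 surrogates per threshold.

`scripts/acceptance.R` recomputes the small-worldness bound from scratch
on a fresh seeded cohort and reports the 5th-percentile of per-subject
minimum σ, a single number that exceeds 1 exactly when the 95%-of-subjects
criterion holds.

## Known limitations

* Absolute metric scales depend on the distance and normalization
  conventions above; published tables from other toolboxes are not
  directly comparable.
* The toy tractography is a rule-faithful miniature (voxel-hop, no
  interpolation, no probabilistic variants) intended to validate
  network-construction logic, not to process real DWI volumes.
* Whether real studies restrict Lp to connected pairs or use harmonic
  means, and whether hubs are defined per subject or per group, varies;
  both choices here are explicit and the alternatives are one function
  call away.
* The NBS implementation covers group contrasts with optional covariate
  residualization; general linear model contrasts and threshold-free
  cluster enhancement are out of scope.
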