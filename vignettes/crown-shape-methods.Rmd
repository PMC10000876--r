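---
title: "Methods: outline morphometrics, morphospace tests and 3D crown morphing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline morphometrics, morphospace tests and 3D crown morphing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontomorph)
```

This vignette documents the models and numerical choices behind
odontomorph, in the spirit of a statistical-methods supplement: what
each stage assumes, which parameters matter, and where the design was
genuinely open.

## Outline analysis

### Model

A crown silhouette is an ordered loop of 2D points in mm. The loop is
treated as closed (the edge from the last point back to the first is
implicit), forced counter-clockwise by a signed-area test so that
chirality conventions are uniform across specimens, and resampled to
`n_points` (default 64) points equally spaced along the polygonal arc.

The elliptic Fourier transform is implemented in the chain
(Kuhl–Giardina) formulation: the increments of x and y are decomposed as
functions of cumulative chord length t along the loop, with period the
perimeter T. This choice makes the forward transform *exact* for a
polygon (no quadrature error) and independent of how densely the
underlying curve was digitized. Each harmonic n yields four
coefficients; the constant terms A0, C0 (the arc-length centroid) are
kept only for reconstruction.

### Normalization

Size, orientation and starting point are standardized from the
first-harmonic ellipse: the start phase θ is moved to the tip of the
semi-major axis, the shape is rotated so that axis lies on +x, and all
coefficients are divided by the semi-major axis length. Two details are
easy to get wrong and are therefore fixed explicitly:

* θ from the closed-form arctangent may point at the semi-*minor* axis;
  of the two candidates θ and θ + π/2 the one giving the longer first
  semi-axis is taken.
* θ is then still defined only modulo π (the two tips of the major
  axis). The residual flip negates every even harmonic while leaving
  odd harmonics — including the first — unchanged, so no rule based on
  the first harmonic can resolve it. The package picks the
  representative whose largest-magnitude even-harmonic coefficient is
  positive. For shapes whose even harmonics all vanish (circles,
  ellipses, perfectly 2-fold-symmetric outlines) the two representatives
  coincide, so the rule is vacuous exactly when it is unneeded.

Normalization deliberately does **not** remove reflection: left and
right antimeres are genuinely chiral, and a mirrored outline yields
different normalized coefficients. Users analyzing bilateral data must
either mirror one side explicitly or rely on the per-animal averaging
described below.

### Shape variables and tests

After normalization A1 = 1 and B1 = C1 = 0, so the first harmonic
carries no shape information and is dropped; H harmonics give 4(H − 1)
variables. The defaults H = 9 (upper first molars, 32 variables) and
H = 5 (lower, 16 variables) follow the conventional
error-versus-information compromise for murine molars; both are
configurable and the package does not re-derive the compromise.

PCA is computed on the covariance matrix — the coefficients share one
dimensionless unit after normalization, so correlation-scaling would
only inflate noise axes. Component signs are fixed by forcing each
component's largest-magnitude loading positive, making results
deterministic across platforms. The leading axes reaching 95% cumulative
variance are retained (threshold configurable; the comparison uses a
1e-12 slack so that an exact boundary like 19 × 0.05 counts as reached).
The retained-axis count is additionally capped at N − 2 so the exact
two-group F transform below stays well-defined.

Retained principal coordinates are rank-transformed column-wise with
midranks for ties — the scores are not plausibly multinormal, and ranks
make the test invariant to any monotone distortion of the coordinates.
Wilks' Λ = det(W)/det(W + B) is computed from the within- and
between-group cross-product matrices on the ranks, and converted with
the exact two-group transform F = ((1 − Λ)/Λ)((N − p − 1)/p) on
(p, N − p − 1) degrees of freedom; for two groups this is the Hotelling
T² identity, not an approximation, and the test suite checks it against
both a hand-computed T² and `stats::manova`. A singular within-group
matrix (more retained axes than the data support) raises an error
suggesting fewer axes rather than silently regularizing.

### Bilateral teeth

Published per-animal degrees of freedom imply one observation per
animal, but the treatment of left/right sides is not stated anywhere we
could follow; the pipeline therefore exposes a switch. With
`reduce_sides = TRUE`, normalized coefficient vectors are averaged
within animal (after which the first-harmonic entries are re-clamped to
the exact identity pattern); with the default `FALSE`, each outline is
an observation. The demo analyses simulate one outline per animal, so
the switch is a no-op there.

## Synthetic data

The generators define the study conditions under which the package's
claims are tested; they are ordinary exported functions, not test
scaffolding.

* **Outlines** are star-shaped radius functions: an ellipse (default
  semi-axes 1.1 × 0.75 mm, a mouse-upper-first-molar footprint) plus
  Gaussian cusp bumps (five bumps, amplitudes 0.12–0.16 mm, width
  0.35 rad) plus radial Gaussian noise (sd 0.01 mm, roughly digitizing
  error at a 7–8 µm voxel scale). The genotype effect shifts cusp 1 by
  `dtheta1` radians (0.3 rad in the demo conditions, a linguo-distal
  repositioning) and may rescale its amplitude. Noise is radial so the
  curve remains simple and closed; star-shapedness is an accepted
  limitation — real crown outlines with deep re-entrants are not in the
  generator's repertoire, so passing tests speak to cusp-position
  effects, not to arbitrary outline topology.
* **Crown meshes** are elliptic domes (footprint 1.0 × 0.8 mm, height
  0.5 mm) plus four Gaussian cusps named c5, c6, c8, c9, triangulated
  on a regular grid (default 48 × 48). Landmarks are placed at local
  maxima of the analytic height function, refined numerically from the
  cusp centers — the apex trails a genotype shift of the center
  slightly because the dome gradient pulls it inward, and tests use the
  analytic argmax as the oracle, not the naive center.
* **Morphotypes** are independent per-side Bernoulli draws; default
  probabilities are the observed cohort frequencies of the packaged
  scoring table (39/66, 40/66, 20/66 for mutants; 0 for wild types).
* **Counts** are negative-binomial with variance mean + φ·mean²;
  φ = 0 falls back to Poisson. A `de_fraction` of genes has its
  second-group mean multiplied by 2^log2fc with alternating sign.

All generators are pure functions of (parameters, seed); seeding uses
`withr::with_seed`, so no global RNG state leaks.

## 3D morphing

### Alignment

Landmark alignment is the closed-form least-squares similarity fit
(SVD-based, with the determinant correction that excludes reflections).
Collinear landmark configurations are rejected — with only three or
four cusp landmarks this is a real failure mode, not a theoretical one.
ICP refinement is point-to-plane with a Rodrigues update, keeps the
initial scale fixed, rejects any step that would increase the RMS (so
the reported RMS history is non-increasing by construction), and stops
at an RMS improvement below 1e-6 mm or 100 iterations.

### Correspondence and displacement field

"Minimum projected distance" is realized as ray casting from each
source vertex along its area-weighted vertex normal, in both
directions, taking the nearest intersection within the cutoff (default
5× the mean source edge length — generous enough to bridge cusp-scale
shape differences, tight enough not to jump to the far side of a
crown). Vertices whose ray misses fall back to the nearest point on the
target surface within the same cutoff; the remainder are "in-between
positions" filled by iterative neighbor averaging (discrete Laplacian
relaxation) of the matched target points over the source mesh graph,
iterated to a 1e-9 fixed point. All queries run against a uniform grid
over triangle bounding boxes, so the procedure scales to meshes in the
10^5-triangle range without compiled code.

One property of this construction deserves emphasis: a purely lateral
shift of a surface feature is encoded mostly as *normal* motion (the
old apex moves down, the flank moves up), not as a tangential vector
pointing from old to new apex. That is faithful to projection-based
correspondence in general and is why the displacement-transfer tests
that need a tangential field construct it analytically.

The displacement field is target point minus source vertex; vertices
near the cervical margin (by default the lowest 15% of the crown height
range, configurable) are pinned to zero so the crown base stays put.

### Transfer to a homologous mesh

The third mesh is brought into the source frame by the cusp-landmark
similarity transform; each vertex samples the field at its nearest
point on the source surface with barycentric interpolation and is
mapped back to its native frame, which rescales the displacement by the
inverse alignment scale. Vertices farther from the source surface than
the cutoff receive zero displacement. Whether the published procedure
applied one global field or one transformation per cusp is ambiguous;
both are provided: `mode = "global"` (dense sampling, the default) and
`mode = "per_cusp"`, which partitions the source surface by nearest
paired landmark, averages one transformation vector per cusp region,
and applies a distance-weighted blend — the coarser, cusp-level reading.

### Surface averaging

The height-map averaging implements the three logical steps of building
a representative crown from many scans: least-squares superimposition
(integer-cell in-plane shift plus z offset, with corrections *centered*
across maps so the reference defines orientation but not a position
bias — this is what makes the average of two z-offset copies the
midsurface rather than the reference), dense 2D displacement estimation
to the reference, and cell-wise averaging of corresponded x, y, z with
fixed-point inversion of the mean in-plane motion back onto a regular
lattice. The displacement estimator is a standard multi-resolution
Horn–Schunck-style solver (coarse-to-fine with warping, 4-neighbor
regularization) written for this package; the proprietary optical-flow
algorithm referenced in the motivating workflow is not reproducible
from its description, and this component should be read as a standard
stand-in implementing the same role. The smoothness weight α defaults
to 0.25 (z in mm on cell-unit gradients): strong enough to keep the
field coherent across the featureless dome, weak enough to let
cusp-scale features move several cells. Averaging corresponded
coordinates rather than raw cells is the discriminating property — a
bump shifted ±0.2 mm between two maps stays a single full-height bump
near the midpoint, where naive averaging yields two attenuated ones.

## Crown statistics

* The DE-marking rule's "fold change ≥ 0.5" is read on the log2 scale
  in absolute value (a linear fold change ≥ 0.5 would be vacuous for
  upregulated genes); both the threshold and the scale are arguments,
  so the linear reading is one switch away. "Half of the samples" is
  ceiling(group size / 2), evaluated per group.
* The t test is the pooled-variance form with the statistic signed by
  mean(x) − mean(y); the degenerate zero-variance case returns t = 0,
  p = 1 for equal means rather than erroring. The variance test is the
  two-sided F ratio. Both delegate to `stats::t.test` / `stats::var.test`
  and are verified against hand-computed closed forms on toy samples.
* Fisher enrichment delegates to `stats::fisher.test`; the test suite
  cross-checks it against an explicit hypergeometric enumeration.
* Morphotype frequencies count specimen-*sides*; sides scored as
  missing leave the denominator. An empty cohort reports 0/0 with an
  undefined (NA) percentage rather than 0%.

## Problem sizes and tolerances

The shipped tests and the acceptance script use: 64-point outlines with
9 harmonics; cohorts of 30 per group; 200 replicates for the type-I
error simulation (the binomial standard error at rate 0.05 is then
about 0.015, which is what the accepted band [0.02, 0.09] reflects);
crown meshes at 40 × 40 grid resolution (1600 vertices); and 41 × 41
height maps at 0.05 mm spacing. These sizes were chosen so each claim
is tested at meaningful power while a full run stays in the tens of
seconds; the algorithms themselves carry no such limits, and the
spatial indexing keeps dense correspondence practical at the
quarter-million-triangle scale of real microCT crowns.

Numerical tolerances follow one rule: identities (round trips,
invariances, oracle agreement) are asserted near machine precision
(1e-9 to 1e-6 mm), while statistical and geometric recovery claims use
the uncertainty implied by their own sampling (binomial bands,
percentage-of-effect bounds).

## Known limitations

* Outlines must be star-shaped for the generator and simple closed
  curves for the analysis; self-intersecting digitizations are not
  repaired.
* EFA normalization assumes a well-defined first-harmonic ellipse;
  nearly circular crowns make orientation and start-point unstable
  (the invariance guarantee degrades gracefully but is not exact
  there).
* The rank-transformed MANOVA is exact-F under exchangeability, not a
  permutation test; very small cohorts with heavy ties may deviate
  from nominal levels.
* Mesh correspondence is one-directional (source → target) as
  specified; symmetric consistency is not enforced.
* Height-map superimposition estimates shift and z offset but not
  in-plane rotation; maps should be roughly co-oriented first (ICP on
  meshes, or the landmark alignment, covers that use case).
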