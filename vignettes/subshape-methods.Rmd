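---
title: "Surface-based morphometry of subcortical shapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based morphometry of subcortical shapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`subshape` implements a vertex-wise surface-based morphometry (SBM)
pipeline for small, tube-like subcortical structures such as the
hippocampus and the amygdala, together with a synthetic-cohort generator
that provides ground truth for calibration and recovery testing. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the synthetic experiments
do and do not demonstrate about real imaging data.

## Pipeline overview

Each subject enters as a closed, genus-zero triangular surface mesh in a
common spatial frame (millimetres). The stages are:

1. **Surface conditioning** — quadric-error simplification and Loop
   subdivision smooth segmentation noise while preserving topology.
2. **Conformal tube parameterization** — the surface is mapped onto a
   fixed `nu x nv` parameter grid; each node carries the 3D position, the
   conformal factor `lambda` (local area-distortion density) and the mean
   curvature `H`.
3. **Fluid registration** — each subject's two-channel `(lambda, H)`
   "conformal representation" is registered to a template's by a viscous
   fluid flow that ascends mutual information (MI), yielding a dense
   displacement field and its Jacobians.
4. **Morphometry features** — per vertex: radial distance (RD, a
   thickness surrogate), the Jacobian determinant (TBM), the log-Euclidean
   deformation tensor (mTBM, a 3-vector), and their combination MMS
   (4-vector: RD plus mTBM).
5. **Vertex statistics** — two-sample t (RD, TBM) or Hotelling's T²
   (mTBM, MMS) per vertex, permutation p values with a count-based global
   correction, atrophy/expansion direction maps, and Pearson correlation
   maps against clinical scores.
6. **Classification** — random square patches of the MMS grid, sparse
   coding under a learned over-complete dictionary, max pooling, and a
   GentleBoost tree ensemble evaluated by 10-fold cross-validation with
   ACC/SEN/SPE/PPV/NPV.

## Conformal grid

The parameter domain is the rectangle `[0, 1] x [0, 2*pi)`: `u` runs along
the structure's long axis, `v` is periodic around it. The default grid is
`100 x 150 = 15,000` nodes; tubes are longer than they are round, so the
around-axis direction gets the larger count. Grids are sampled at
`u_i = (i - 0.5)/nu` (midpoint rule, so the integral of `lambda` over the
grid reproduces the surface area) and `v_j = 2*pi*(j-1)/nv`.

For a general mesh, `conformal_parameterize()` proceeds as follows. The
two extremal vertices along the first principal axis of the vertex cloud
are the cut points (near-ties are resolved toward the axis, then by vertex
index, making the cut deterministic); removing their vertex stars leaves
an open tube with two boundary loops. `u` is the discrete harmonic
function (cotangent Laplacian) with Dirichlet values 0 and 1 on the
loops. `v` is obtained by cutting the tube along the shortest geodesic
between the loops and solving a second harmonic problem in which the
duplicated seam vertices are constrained to differ by `2*pi` — a discrete
harmonic conjugate with the correct period. Positions are resampled at
the regular grid by barycentric interpolation in the parameter plane;
injectivity is checked by counting flipped parameter triangles and the map
is rejected if more than 2% flip (in practice zero for tube-like input).

The conformal factor is defined as `lambda = sqrt(det g)` of the resampled
immersion per unit parameter area — an area-distortion density whose grid
sum reproduces the total surface area to within 1% on smooth shapes. The
normalization is recorded in the grid metadata so registration is
internally consistent; only relative variation matters downstream because
registration channels are standardized. Mean curvature uses the
cotangent-Laplacian mean-curvature normal over Meyer's mixed Voronoi
areas, signed against the outward normal (a sphere of radius `r` has
`H = 1/r` everywhere); vertices with triangle angles below 0.5 degrees are
flagged and replaced by their one-ring average.

One caveat is deliberate: the `(lambda, H)` pair determines a surface up
to rigid motion in the continuous setting; the tube harmonic map used here
is this package's committed discrete interpretation, chosen for
determinism and robustness on elongated subcortical shapes rather than
spherical-harmonic machinery.

## Fluid registration

Registration operates on the standardized `(lambda, H)` images of subject
and template. The similarity is the **sum of per-channel mutual
information** — channels are standardized to zero mean and unit variance
first, so neither dominates the histograms. Two estimator details matter:

* The **ascent direction** is the smooth Parzen-style gradient: the
  derivative of the linear intensity-bin weights of the warped (bilinearly
  interpolated) subject image times its spatial gradient. This direction
  is kink-free even at integer displacements.
* **Progress is measured** on the classical partial-volume histogram
  (spatial bilinear weights into hard intensity bins), *corrected for
  interpolation dispersion*: the same histogram computed for the template
  against itself at the same displacement measures exactly the entropy
  sharpness lost to fractional sampling, and adding it back leaves a
  metric whose gains reflect alignment only. At zero displacement the
  correction vanishes, which makes subject == template an exact fixed
  point (the identity-registration test asserts `det J = 1` to 1e-6).

Each iteration smooths the force with a Gaussian of width `sigma_fluid`
(the standard fluid approximation of the viscous PDE solve — an explicit
Navier-Stokes solver is intentionally not used), scales the explicit Euler
step so the largest update is at most half a grid cell, and accepts the
step only if the corrected MI increases (rejections halve the step; ten
consecutive rejections mean convergence). When the incremental flow's
`det J` falls below `regrid_threshold` the flow is composed into the total
displacement and restarted — classical regridding, which is what lets the
total deformation grow large while each increment stays diffeomorphic. A
coarse-to-fine pyramid (factor-2 downsampling) handles displacements of
several cells. The u-component of the displacement is pinned to zero on
the first and last grid rows: the cut points correspond across subjects by
construction.

Defaults (`registration_params()`): 32 histogram bins, `sigma_fluid = 2`
grid cells, 3 pyramid levels, 200 iterations per level,
`regrid_threshold = 0.5`, relative MI tolerance `1e-5`. These are
conventional fluid-registration settings; all are configurable. The MI
trace is stored per accepted step together with a segment index — the
metric scale changes at pyramid-level switches and regrid events, so
monotonicity holds within segments, not across them.

A practical note on identifiability: a nearly rotationally symmetric tube
carries almost no information about displacement around its axis (the
aperture problem), so registration accuracy is assessed on surfaces with
realistic shape texture (the generator's smooth noise provides it), where
a synthetic warp of up to 2–3 cells is recovered with mean endpoint error
well under half a cell.

## Morphometry features

* **RD** — the medial-axis point of the iso-parametric ring `u = const`
  is the ring's 3D centroid (for tubes the ring is perpendicular to the
  medial axis, so the centroid lies on it); RD is the node's distance to
  its ring centroid, in mm. RD is computed on the subject's own grid; the
  registration provides the cross-subject node correspondence.
* **TBM** — `det J` of the registration at each node: below 1 is local
  contraction, above 1 expansion. Statistics run on `det J` itself (a log
  option exists for symmetry-sensitive analyses).
* **mTBM** — `log(J J^T)` via the closed-form eigendecomposition of the
  symmetric 2x2 tensor, vectorized as `(L11, sqrt(2) L12, L22)`. The
  `sqrt(2)` makes the Euclidean norm of the 3-vector equal the Frobenius
  norm of the matrix logarithm, i.e. Euclidean distance on mTBM vectors
  is the Log-Euclidean metric on deformation tensors.
* **MMS** — the 4-vector `(RD, mTBM)`: radial plus tangential
  information. Channel 1 is RD bitwise.

The identity `det(J)^2 = exp(L11 + L22)` links TBM and mTBM and is
asserted in the tests to 1e-8.

## Permutation statistics

Group comparisons are never parametric: the observed statistic per vertex
(pooled-variance t, or Hotelling's T² with pooled covariance and a
`1e-8 * trace(S)/d` ridge when singular) is ranked against `n_perm` label
shuffles. One shuffle is shared by **all** vertices of a permutation,
preserving the spatial dependence of the maps; an instrumentation hook
exposes each permutation's label vector so tests can verify the contract.
t-based p values use `|t|` (two-sided — the direction of an alteration is
reported separately); T² is inherently one-sided.

The global correction mirrors the count statistic: the "real effect" is
the number of vertices with uncorrected `p < alpha`; the same count is
computed for every permutation against the permutation distribution
(leave-self-in — the difference from leave-self-out is of order
`1/n_perm`), and the corrected global p is the fraction of permutations
whose count strictly exceeds the real effect (ties favour significance).
A zero global p is reported as `< 1/n_perm`. All p values are exact
multiples of `1/n_perm`.

Direction maps label significant vertices of a univariate measure by the
sign of the reference-group mean minus the comparison-group mean:
positive (reference larger) is atrophy of the comparison group, negative
is expansion. Clinical correlation maps are vertex-wise Pearson r against
a score with the two-sided parametric p, masked at an uncorrected 0.05 —
deliberately uncorrected, as exploratory projection maps.

Hotelling's T² under permutation is fully vectorized: per-vertex moment
sums are permutation-updated by one matrix product, and the quadratic
form `d' S^{-1} d` is evaluated element-wise with closed-form symmetric
inverses (direct for d <= 3, 2x2-block Schur complement for d = 4), so
10,000 shuffles over 15,000 vertices stay tractable without compiled code.

## Sparse-coding classification

MMS grids are cut into `n_patches` random square windows (default 1008;
window sides 20–30 vertices at full grid resolution) shared across
subjects; each patch is flattened to a `side^2 * 4` vector. Within each
cross-validation fold, training patches are standardized (dimension-wise
centring, global scaling to unit mean patch norm — so the sparsity weight
`gamma` is a fraction of a typical atom correlation) and an over-complete
dictionary is learned by Stochastic Coordinate Coding: samples stream in
shuffled order; each sample's code takes a few coordinate-descent passes
restricted to its correlated atoms; only the support columns receive a
stochastic gradient step with a count-decayed learning rate and are
renormalized. Atoms are warm-started from jittered random training
samples. The dictionary is re-learned inside every training fold — the
paper-style pipeline is silent on this point, and re-learning is the
leakage-free choice.

Encoding solves the full LASSO per patch by covariance-space coordinate
descent to a relative objective tolerance of 1e-8 (verified against an
independent FISTA solver to 1e-5); an optional least-squares debiasing
refits the support coefficients, which is how reconstruction quality is
assessed in the dictionary-recovery tests (the l1 shrinkage is deliberate
for selection, not for reconstruction). Subject vectors apply 2x2 max
pooling with stride 2 to the patch-by-atom code matrix and flatten
(a global per-atom max is available as the alternative pooling
interpretation; the report records which was used).

GentleBoost uses depth-limited `rpart` regression trees as weak learners:
weights start uniform, each round fits the weighted squared error to the
±1 labels, adds the (clamped) prediction to the ensemble score, and
multiplies weights by `exp(-y f)`. Cross-validation allocates subjects to
near-equal folds (311 subjects give nine folds of 31 and one of 32),
trains everything — standardization, dictionary, booster — on the
training folds only, and reports per-fold and mean ACC, SEN, SPE, PPV,
NPV (positive class = second factor level). Single-class folds yield NA
metrics, excluded from means with a warning. Classes are deliberately not
rebalanced. A patch-size sweep helper reruns the pipeline over a range of
window sides and reports accuracy per side.

Defaults: `k = 32` atoms (over-complete relative to the pooled inputs at
the reduced grids used throughout), `gamma = 0.15`, 5 SCC epochs, 50
boosting rounds of depth-3 trees. The dictionary size and sparsity weight
have no canonical values in the SBM literature; these were fixed once for
the desk-scale grids and are all configurable.

## The synthetic cohort generator

`make_template_surface()` provides two analytic templates:
`hippocampus_like` (a tube of varying elliptical cross-section swept
along a C-shaped circular arc, radius profile pinched closed at both
ends) and `amygdala_like` (a superellipsoid-like body of revolution with
elliptical cross-section). Both are generated together with their exact
parameterization, so the pipeline can be exercised with or without the
discrete parameterization stage. Dimensions are millimetres at the scale
of the human structures (hippocampal arc ~36 mm, maximal radius ~5 mm;
amygdaloid half-axes 9/7/5.5 mm).

`simulate_cohort()` deforms the template radially per subject:

* **Smooth shape noise** — a low-order harmonic field (bands <= 8 in u
  and v, spectrum decaying as `1/(1+k+l)`), tapered to zero over the
  outer 12% of `u` so the pinched ends stay closed, then rescaled so the
  grid-wide standard deviation equals `noise_sd` (default 0.3 mm). The
  constant term is excluded: global size differences are assumed removed
  by the 9-parameter normalization that precedes SBM pipelines, and no
  rigid/scale jitter is applied by default for the same reason.
* **Group effects** — each region is a parameter rectangle with a signed
  radial offset `delta` (atrophy shrinks the radius) applied along the
  radial direction with full strength in the core and a raised-cosine
  falloff over the outer 25% of each side. The first-listed group is the
  reference and receives no effect. Offsets are radial because RD and the
  direction maps are radial constructs; tangential effects can be added
  by parameter-domain warping where tensor-feature recovery is the
  target.
* **Scores** — per score, a target Pearson correlation `rho` with the
  subject's realized mean deformation inside the effect regions;
  generated as `mean + sd * (rho * z + sqrt(1-rho^2) * noise)` with `z`
  the standardized realized deformation.

Ground truth (`effect_mask`, `true_delta`, per-subject deformation) is
returned alongside; masks depend only on the configuration, not the seed.
Subjects whose radius would cross the medial axis are rejected — the
generator refuses to build self-intersecting surfaces.

No effect sizes in millimetres exist in the SBM literature for these
structures; the defaults used in the recovery experiments
(`delta` in 0.3–1.5 mm, i.e. 1–5 times the noise level) were chosen to
span weak-to-strong recovery regimes, not to mimic any disease effect.

A design point worth stating explicitly: a one-sided radial offset moves
the ring centroid, so RD changes off the implanted region as well — the
medial axis itself shifts. That is a genuine property of centroid-relative
thickness measures, not an artifact. The recovery experiments therefore
implant **antipodal region pairs** (the same offset at `v` and `v + pi`),
which cancels the first moment and keeps the medial axis fixed, isolating
local thinning. Single-region effects remain available and are what the
direction-map examples use.

## Problem sizes and calibration experiments

The shipped tests and the acceptance script run at reduced grids chosen
as the package's own desk-scale testing conditions:

* Null calibration: two groups of 30 subjects, a 30x40 grid of iid
  Gaussian features, 2,000 shuffles; the per-vertex significant fraction
  is checked against 0.05 within three binomial standard errors, and the
  corrected global p across 20 replicate null cohorts is checked for
  excess below 0.05 at the binomial 99.9% bound.
* Atrophy recovery: `delta = 3 * noise_sd` (0.9 mm vs 0.3 mm) in an
  antipodal region pair on a 30x40 grid, 2x30 subjects, 500 shuffles;
  significant-mask/truth-mask Dice is required above 0.5 (observed ~0.8)
  with correct atrophy labels and monotone statistic growth in `delta`.
* Registration recovery: a smooth synthetic warp of up to 2 grid cells
  on a textured 40x60 subject, recovered with mean endpoint error below
  0.5 cells and `det J > 0` everywhere.
* Classification: 2x30 subjects, 40x60 grids, 60 patches of side 10,
  `k = 32`, 10-fold CV; mean accuracy above 0.85 on a strongly separable
  cohort and collapse to 0.5 ± 0.1 under label shuffling.

What passing these experiments shows: the statistics are calibrated at
their nominal levels, implanted effects of known geometry are recovered,
and the feature-to-classifier chain carries group signal without leakage.
What they do not show: robustness to segmentation error, to topology
defects of real meshes, to anatomy-specific subfield geometry, or that
any particular disease contrast will be detected — the generator's
smooth, radially-deformed tubes are intentionally simpler than real
subcortical surfaces.

## Known limitations

* The parameterization targets tube-like genus-zero surfaces; flat or
  branched shapes will fail the injectivity check (by design, with a
  structured error).
* The harmonic `(u, v)` map is not exactly conformal on coarse meshes;
  `lambda` is defined as the actual area density of the resampled
  immersion, so downstream consistency does not depend on exact
  conformality.
* The fluid solver is the Gaussian-smoothed approximation, not a full
  viscous PDE solve; very large or sliding deformations are out of scope.
* Hotelling permutations above 4 channels would need a generic solver
  (the element-wise inverses stop at d = 4, the MMS dimension).
* GentleBoost relies on `rpart` weak learners; exact reproduction of
  other tree implementations' split tie-breaking is not attempted.
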