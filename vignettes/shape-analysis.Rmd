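---
title: "Statistical shape modelling of subtalar joint bones with tarsalSSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of subtalar joint bones with tarsalSSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarsalSSM)
```

## The problem

Chronic ankle instability (CAI) — recurrent giving-way and re-sprains
after a first lateral ankle sprain — has many proposed risk factors, and
the three-dimensional shape of the subtalar joint bones (talus and
calcaneus) is one of them. To compare bone shapes between groups of
subjects one needs a representation in which "the same" anatomical
location is measured on every bone. `tarsalSSM` implements the standard
statistical-shape-model (SSM, or point-distribution-model) workflow for
this problem:

1. **Normalisation** — each segmented bone surface is sampled into a
   point cloud, translated to the origin and scaled to unit centroid
   size (Kendall's size measure: the square root of the summed squared
   distances of the points from their centroid). Right-side bones are
   mirrored in the sagittal plane so left and right anatomy share one
   shape space.
2. **Unbiased groupwise registration** — all instances of one bone type
   are aligned by similarity transforms to an *evolving mean* point
   cloud modelled as a Gaussian mixture, so that no single specimen is
   privileged as the reference.
3. **Dense correspondence** — a template of N points drawn from the
   converged mean is matched one-to-one into every aligned instance,
   using point coordinates and surface normals, giving a consistently
   ordered instances-by-3N coordinate matrix.
4. **PCA shape model** — the mean shape x̄, orthonormal modes of shape
   variation Φ and their variances λ follow from the eigendecomposition
   of the sample covariance of that matrix. Any shape is
   x = x̄ + Σₛ bₛ Φₛ, and the coefficients b (the *shape parameters*)
   are the per-bone measurements all statistics run on.
5. **Group statistics** — for every retained mode, the b values of the
   three groups (ipsilateral CAI, CAI-contralateral, healthy) are
   screened for normality, compared by one-way ANOVA with Bonferroni
   post-hoc pairwise t-tests, and re-tested with age and gender as
   covariates (ANCOVA).

Because clinical CT cohorts cannot be redistributed, the package ships a
synthetic bone-cohort generator with fully known ground truth, so every
stage — and the pipeline as a whole — is testable at desk scale.

## The registration model

Each normalised instance cloud Y is aligned to the current mean cloud M
by maximising a Gaussian-mixture likelihood: the mean points act as
mixture centroids with a common kernel width σ, plus a small uniform
outlier component (weight 0.01) for robustness. The EM iteration is the
coherent-point-drift scheme specialised to similarity transforms: the
E-step computes soft correspondences, and the M-step has a closed-form
weighted Umeyama solution for rotation, isotropic scale and translation.
After every instance is re-aligned, each mean point is re-estimated as
the responsibility-weighted average of the matched instance points, with
a proximal term λ that pulls the update towards the previous mean
(larger λ — a stiffer, more slowly evolving mean). Finally the mean is
re-centred and re-scaled to unit centroid size, which removes the global
drift that would otherwise accumulate — the "unbiasedness" constraint.

Parameter choices and their rationale:

* `sigma` (default 3 mm) is stated in millimetres and divided by each
  instance's recorded centroid size, so it keeps its physical meaning on
  the dimensionless unit-size clouds. It is the *initial* kernel width:
  on a cold start the width is first widened to the data spread (the
  classic coherent-point-drift initialisation, needed to escape initial
  misalignments of tens of degrees) and then re-estimated each EM
  iteration by the closed-form update. We do not keep σ fixed at 3 mm
  throughout because a fixed width cannot both escape a 30° initial
  rotation and resolve sub-spacing alignment detail; `annealSigma =
  FALSE` restores a fixed-width EM if wanted.
* The annealed width is floored at `sigmaFloorFactor` (default 0.5)
  times the mean cloud's median nearest-neighbour spacing. Without a
  floor the width collapses towards zero, responsibilities become hard
  assignments, and the barycentric mean update wanders indefinitely
  along the surface; the floor keeps the mean update a stable, smooth
  contraction.
* `lambda` defaults to 1e-6 (the published talus setting; 5e-4 for the
  calcaneus). At these magnitudes it is a gentle regulariser; the mean
  update is dominated by the data.
* Convergence is declared when the relative Frobenius change of the
  mean falls below `tol` (1e-6) **or** the aligned poses stop moving —
  RMS per-point motion between consecutive outer iterations below
  `tolAligned` (1e-5). The second criterion exists because the mean
  cloud keeps diffusing tangentially along the surface (at a slowly
  decaying ~1/t rate) long after every pose, and hence every downstream
  quantity, is stable; demanding 1e-6 of the mean itself would burn
  hundreds of iterations changing nothing that matters.
* The scale estimate needs special care. Because size has already been
  removed by centroid-size normalisation, the aligned scale must sit
  near the RMS-radius ratio between instance and mean clouds (which
  only differs from 1 through the point-count difference). During the
  wide-kernel phase the closed-form scale update degenerates towards
  the blurred centroid — the well-known scale-collapse pathology — so
  the scale is held at the RMS-radius reference until the kernel has
  annealed below 0.3 of the mean cloud's RMS radius, and is thereafter
  clamped to [0.7, 1.4] times that reference. Without this, occasional
  instances collapse or freeze in grossly rotated poses and contaminate
  the shape model with a spurious misalignment mode.
* Per-instance initial alignment is the identity (with the scale set to
  the RMS-radius ratio between instance and mean clouds). Anatomically
  oriented scans arrive in roughly a common orientation, and the study
  conditions bound rotations at 30°, well within the EM basin. A
  principal-axes initialisation (`initMethod = "principal-axes"`) is
  available for data with large unknown rotations, but it is not the
  default: for nearly symmetric bones the axis-sign disambiguation can
  pick a 180°-flipped pose, which is far worse than starting from the
  identity.

## Correspondence

The published correspondence method for these bones matches points
using coordinates *and* surface normals. `tarsalSSM` implements that
contract as a combined-cost linear assignment: template point t and
instance point i cost ‖p_t − p_i‖² + w·‖n_t − n_i‖², with `normalWeight`
w = 0.1 by default (coordinates on unit-size clouds, unit normals). A
strict one-to-one matching is enforced by solving the rectangular linear
assignment problem (a Jonker–Volgenant-style shortest-augmenting-path
solver in C++); candidate pairs are the 20 positionally nearest
neighbours per template point, with prohibitive costs elsewhere, which
keeps the problem effectively sparse while the solver guarantees a
feasible, globally optimal assignment. The template is a seeded
subsample of the mean cloud; when more corresponded points are requested
than the mean has (as when a 2,000-point mean must carry a denser
correspondence), the template is upsampled by midpoint interpolation
between neighbouring mean points.

## The shape model

PCA is computed through the SVD of the centred correspondence matrix —
exact, and far cheaper than forming the 3N × 3N covariance when N
reaches thousands of points. Eigenvalues use the n − 1 divisor;
eigenvector signs are pinned (largest-magnitude entry positive) so that
b values are reproducible run to run. Mode retention follows the strict
"more than 5% of total variance" rule, with a floor of one mode. Shape
parameters are reported both raw and in SD units (b/√λ), since published
subject-level values are customarily quoted in SD units.

## Group statistics

* **Normality screen**: a one-sample KS test against a normal with the
  *estimated* mean and SD is anti-conservative; the p-value is therefore
  taken from a Monte-Carlo Lilliefors null (10,000 simulated samples per
  sample size, memoised). This is a deliberate, documented deviation
  from the naive KS recipe.
* **ANOVA / post-hoc**: one-way fixed-effects ANOVA per mode; pairwise
  two-sample t-tests with the variance pooled across all three groups
  (the classic Bonferroni post-hoc), raw p-values multiplied by 3 and
  capped at 1. No multiplicity correction is applied across modes,
  matching standard practice in this literature; mode-level findings
  should be read accordingly.
* **ANCOVA**: b ~ group + age + gender per mode, group effect tested by
  the extra-sum-of-squares F-test against the covariate-only model.
  Degenerate covariates (single gender, constant age) are dropped with a
  warning.
* **Non-independence**: the three groups share subjects — each CAI
  patient contributes an ipsilateral and a contralateral ankle, and
  bilateral healthy controls contribute both ankles. The implementation
  mirrors the field's independent-groups treatment but warns about it,
  and `healthyPolicy = "one-per-subject"` restricts healthy controls to
  one ankle each. Which healthy ankles should enter is genuinely
  ambiguous; both policies are provided and the default ("both") keeps
  the 98-instance design.

## The synthetic cohort generator

`generatorConfig()` describes a virtual study population; its defaults
*are* the emulated study conditions and are not tuning knobs:

* 26 unilateral CAI subjects (ipsilateral + contralateral instance
  each), 26 healthy controls of whom 20 contribute both ankles and 6 one
  ankle — 98 instances.
* The template bone is a superellipsoid (semi-axes 30 × 22 × 18 mm,
  exponent 2.5 — a compact tarsal-bone-sized blob) warped by six smooth
  seeded radial bumps of relative amplitude 0.08, triangulated on an
  icosphere (2,562 vertices by default; the test suite uses the 642
  vertex level).
* Shape variation lives in k = 4 orthonormal smooth deformation fields
  (low-order spherical-harmonic profiles times radial/axis directions,
  QR-orthonormalised over the vertices) with strictly decreasing
  variances (400, 200, 100, 50) mm². With unit-norm fields this puts a
  few millimetres of shape SD on the surface — the scale of real
  tarsal-bone variation relative to a ~25 mm bone.
* The group difference is a mean offset of `effectSize` SD on one
  designated mode, identical in ipsilateral and contralateral instances
  by default (`contraFraction = 1`), encoding the observation that bone
  shape does not differ between the two ankles of a unilaterally
  unstable subject. A fraction parameter lets simulations explore
  partial contralateral involvement.
* Measurement noise (SD 0.1 mm) is applied along vertex normals —
  surface-measurement-like — rather than isotropically.
* Poses are random similarity transforms (rotations up to 30°,
  translations up to 20 mm, scale 0.8–1.2); right-side instances are
  mirrored. Ages are uniform per group (18–50 years for patients, 20–55
  for controls, echoing patient groups being younger), gender is
  Bernoulli(0.5), and an optional `confoundAgeSlope` couples age into
  the effect mode for confounding studies.

What the generator does **not** emulate: real talar/calcaneal anatomy
(articular facets, necks, tuberosities), segmentation artefacts,
scanner-dependent resolution, or within-subject shape correlation beyond
the planted group structure. Passing tests therefore demonstrate that
the pipeline recovers planted covariance structure and calibrated error
rates under controlled geometry — not that any specific anatomical claim
about real bones is reproduced.

## Numerical choices and degenerate inputs

* Meshes must have ≥ 4 vertices and faces, unit normals (tolerance
  1e-6), and in-range face indices; violations are validity errors.
* A cloud of identical points has zero centroid size and cannot be
  normalised (error). Rank-0 cohorts give a zero-mode model with a
  warning. Constant b vectors give KS p = 0 with a degeneracy warning.
  Reflections are rejected by the transform class; mirroring must be
  explicit.
* Assignment ties in the correspondence are broken deterministically by
  the solver's column order; PCA sign ambiguity is pinned as described.
* Every randomised step takes an explicit seed; the pipeline derives
  stage seeds from one root seed by a fixed affine map, so partial
  reruns reproduce exactly. All seeded helpers restore the caller's RNG
  state.

## Problem sizes used in the tests

The test-suite and acceptance studies run at desk scale, chosen so that
the geometric stages stay well-resolved: 98 instances, 400 surface
points sampled per instance, a 120-point mean cloud, 200 corresponded
points, 20 registration iterations. Below roughly 300 sample points per
instance the registration of this template becomes unreliable and a
spurious misalignment mode can dominate the PCA, so 400 is the smallest
size we consider trustworthy; the registration-recovery checks use 500
points per cloud and a 150-point mean. Real bone studies would use the
published operating point (2,000-point mean cloud, thousands of
corresponded points); nothing in the implementation is specific to the
reduced sizes.

## Known limitations

* The registration is a declared, self-contained EM/GMM construction
  built from the standard ingredients of unbiased groupwise bone
  registration (mixture of Gaussians with width σ, an evolving
  n_m-point mean, trade-off λ, unit-centroid-size normalisation);
  other implementations of this family may differ in detail.
* Likewise the correspondence step realises the
  coordinates-plus-normals matching contract via linear assignment;
  geodesic or spectral correspondence methods are out of scope.
* The statistics treat instances as independent (with a warning), as the
  field does; a mixed-effects treatment of the shared subjects is out of
  scope.
* Modes are compared one at a time at α = 0.05 with no across-mode
  correction, matching the published analysis; users wanting family-wise
  control across modes should adjust externally.

## A minimal run

```{r, eval = FALSE}
cfg <- runConfig(
  generator = generatorConfig(effectSize = 1.5, effectMode = 2L, seed = 42L),
  seed = 42L
)
res <- runPipeline(cfg, outDir = "talus_run")
res             # mode-wise p-values and flags
```

`runStudy()` returns the same results in memory along with every
intermediate object (aligned cohort, correspondence matrix, model,
b-value table), which is what the simulation studies in the test suite
use.
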