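# tarsalSSM

Three-dimensional statistical shape modelling (SSM) of subtalar joint
bones, for musculoskeletal researchers asking whether bone shape —
rather than ligament laxity or muscle control alone — separates people
with chronic ankle instability (CAI) from healthy controls. The package
takes segmented talus or calcaneus surface meshes (or simulates a
cohort of bone-like surfaces with known ground truth), brings them into
a common shape space, and tests, mode by mode, whether the three study
groups — ipsilateral CAI, CAI-contralateral, healthy — differ.

## The model

Every bone instance is reduced to an ordered set of N corresponded
surface points, written as a vector **x** of length 3N. A cohort is
summarised by the point-distribution model

> **x** = **x̄** + Σₛ bₛ **Φ**ₛ ,  s = 1 … c

where **x̄** is the mean shape, **Φ**ₛ are orthonormal modes of shape
variation (eigenvectors of the corresponded-coordinate covariance), the
eigenvalue λₛ is the variance explained along mode s, and the shape
parameters bₛ — often quoted in SD units bₛ/√λₛ — are the per-bone
measurements all group statistics run on. Retained modes are those
explaining strictly more than 5% of the total variance.

The stages that produce the correspondence:

* **Normalisation** — surface sampling, translation to the origin,
  scaling to unit centroid size √(Σᵢ‖pᵢ − p̄‖²) = 1, and sagittal
  mirroring of right-side bones (`sampleSurface`, `centerAndScale`,
  `mirrorSagittal`).
* **Unbiased groupwise registration** — all instances are aligned by
  similarity transforms to an evolving Gaussian-mixture mean cloud
  (kernel width σ = 3 mm, n_m mean points, trade-off λ), re-normalised
  each iteration so no specimen biases the atlas (`groupwiseRegister`).
* **Dense correspondence** — a template drawn from the mean cloud is
  matched one-to-one into every instance by minimising
  ‖Δposition‖² + w·‖Δnormal‖² under a linear-assignment constraint
  (`establishCorrespondence`).
* **Statistics** — per retained mode: Monte-Carlo Lilliefors normality
  screen, one-way ANOVA with Bonferroni post-hoc pairwise t-tests, and
  age- and gender-adjusted ANCOVA (`runComparison`).

A synthetic cohort generator (`generatorConfig`, `sampleCohort`) builds
virtual populations of 26 unilateral CAI subjects plus 26 healthy
controls (98 bone instances) from a superellipsoid-with-bumps template
deformed along orthonormal latent modes, with a group mean offset
planted on one mode — so registration, correspondence, the shape model
and the statistics can all be validated against known ground truth.

## Worked example

Simulate a talus-style cohort with a 1.5 SD group effect planted on
latent mode 2, run the full pipeline, and read the mode-wise result:

```r
library(tarsalSSM)

cfg <- runConfig(
  generator = generatorConfig(
    templateSubdiv = 3L, latentModes = 3L, spectrum = c(400, 200, 100),
    effectMode = 2L, effectSize = 1.5, seed = 11L
  ),
  nSamplePoints = 400L, nMean = 120L, nPoints = 200L,
  maxIters = 20L, seed = 11L
)
study <- runStudy(cfg)
study$comparison
#> ComparisonResult: 2 modes at alpha = 0.05
#>   mode 1: KS p = 0.057, ANOVA p = 0.0000, ANCOVA p = 0.0000, significant: CAI vs HEALTHY; CAI_CONTRA vs HEALTHY
#>   mode 2: KS p = 0.428, ANOVA p = 0.3151, ANCOVA p = 0.3482, significant: -
#>   covariate adjustment changed omnibus flags: no

round(100 * varianceExplained(study$model)[1:4], 1)
#> [1] 21.0 11.3  4.8  2.8

round(study$latentAlignment[2, ], 2)   # planted latent mode vs fitted modes
#> mode1 mode2
#> -0.96 -0.03
```

Reading it: two fitted modes clear the 5% retention rule; the first
(21.0% of total variance) is almost perfectly correlated (|r| = 0.96)
with the planted latent direction, and exactly that mode separates both
patient-side and contralateral bones from healthy controls while the
two ankles of the same patients do not differ — the signature the study
design expects. `runPipeline(cfg, "out/")` writes the same results to
disk (model archive, b-value table, tidy statistics CSV/JSON, run
manifest with config hash and stage seeds).

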