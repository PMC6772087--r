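# the desk-scale study conditions used by the end-to-end simulation
# checks: 26 + 26 subjects (98 bone instances), 200 corresponded points
# per instance, three latent modes with a planted effect on mode 2
studyConfig <- function(seed, effectSize = 0) {
  runConfig(
    generator = generatorConfig(
      nCai = 26L, nHealthy = 26L, nBilateralHealthy = 20L,
      templateSubdiv = 3L, latentModes = 3L, spectrum = c(400, 200, 100),
      effectMode = 2L, effectSize = effectSize, seed = seed
    ),
    nSamplePoints = 400L, nMean = 120L, nPoints = 200L,
    maxIters = 20L, tolAligned = 2e-5, seed = seed
  )
}

# success on one planted-effect replicate: the fitted mode best aligned
# with the planted latent direction is flagged for both patient-vs-healthy
# comparisons but not within subjects
plantedSuccess <- function(study, effectMode = 2L) {
  al <- study$latentAlignment
  best <- which.max(abs(al[effectMode, ]))
  fl <- pairwiseFlags(study$comparison)
  fl[best, "CAI vs HEALTHY"] &&
    fl[best, "CAI_CONTRA vs HEALTHY"] &&
    !fl[best, "CAI vs CAI_CONTRA"]
}
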