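# Fixtures are generated in code; nothing is stored on disk.

# a unit square in the z = 0 plane split into 4 triangles around its centre
unitSquareMesh <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0.5, 0.5, 0)
  )
  f <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  surfaceMesh(v, f, instanceId = "unitSquare")
}

rotationMatrix <- function(axis, angleDeg) {
  ax <- axis / sqrt(sum(axis^2))
  ang <- angleDeg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L, 3L)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# a bone-like fixture mesh shared by registration/correspondence tests
boneTemplate <- function(subdiv = 3L, seed = 7L) {
  makeTemplate(generatorConfig(templateSubdiv = subdiv, seed = seed))
}

# nearest-neighbour RMSD between two clouds with unrelated point order
nnRMSD <- function(a, b) {
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) - 2 * tcrossprod(a, b)
  sqrt(mean(pmax(apply(d2, 1L, min), 0)))
}

# RMSD between identically ordered point matrices
pairRMSD <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# metadata frame mirroring the study design (unilateral CAI patients with
# two instances, healthy controls with one or two)
syntheticMetadata <- function(nCai = 26L, nHealthy = 26L, nBilateral = 20L,
                              seed = 1L) {
  cfg <- generatorConfig(
    nCai = nCai, nHealthy = nHealthy, nBilateralHealthy = nBilateral,
    templateSubdiv = 2L, seed = seed
  )
  sampleCohort(cfg)$metadata
}
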