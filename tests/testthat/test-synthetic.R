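test_that("the template is a closed, watertight, deterministic mesh", {
  cfg <- generatorConfig(templateSubdiv = 3L, seed = 5L)
  t1 <- makeTemplate(cfg)
  t2 <- makeTemplate(cfg)
  expect_identical(vertices(t1), vertices(t2))
  # watertight: Euler characteristic 2 and every edge shared by 2 faces
  ed <- rbind(faces(t1)[, 1:2], faces(t1)[, 2:3], faces(t1)[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2L))
  nE <- length(unique(key))
  expect_equal(nrow(vertices(t1)) - nE + nrow(faces(t1)), 2L)

  # different seeds move the bumps
  t3 <- makeTemplate(generatorConfig(templateSubdiv = 3L, seed = 6L))
  expect_false(identical(vertices(t1), vertices(t3)))
})

test_that("with no bumps the template solves the superellipsoid equation", {
  cfg <- generatorConfig(templateSubdiv = 2L, bumpAmp = 0, seed = 1L)
  tm <- makeTemplate(cfg)
  resid <- rowSums(abs(sweep(vertices(tm), 2L, cfg@semiAxes, "/"))^cfg@exponent)
  expect_lt(max(abs(resid - 1)), 1e-6)
})

test_that("latent deformation fields are orthonormal, smooth and seeded", {
  tmpl <- makeTemplate(generatorConfig(templateSubdiv = 3L, seed = 2L))
  F1 <- makeLatentModes(tmpl, 3L, seed = 9L)
  F2 <- makeLatentModes(tmpl, 3L, seed = 9L)
  expect_identical(F1, F2)
  expect_equal(crossprod(F1), diag(3), tolerance = 1e-8, ignore_attr = TRUE)

  single <- makeLatentModes(tmpl, 1L, seed = 9L)
  expect_equal(sum(single^2), 1, tolerance = 1e-12)

  # smoothness: per-edge displacement difference bounded by
  # 5 x mean edge length x field norm (the fields are unit norm)
  ed <- unique(rbind(faces(tmpl)[, 1:2], faces(tmpl)[, 2:3], faces(tmpl)[, c(3, 1)]))
  el <- sqrt(rowSums((vertices(tmpl)[ed[, 1], ] - vertices(tmpl)[ed[, 2], ])^2))
  for (j in 1:3) {
    f <- matrix(F1[, j], ncol = 3L, byrow = TRUE)
    dEdge <- sqrt(rowSums((f[ed[, 1], ] - f[ed[, 2], ])^2))
    expect_lt(max(dEdge), 5 * mean(el) * 1)
  }

  expect_error(makeLatentModes(tmpl, 100L, seed = 1L), "basis size")
})

test_that("the sampled cohort reproduces the study's instance structure", {
  cfg <- generatorConfig(
    nCai = 26L, nHealthy = 26L, nBilateralHealthy = 20L,
    templateSubdiv = 2L, seed = 3L
  )
  cohort <- sampleCohort(cfg)
  meta <- cohort$metadata
  expect_equal(nrow(meta), 98L)
  expect_equal(sum(meta$group == "CAI"), 26L)
  expect_equal(sum(meta$group == "CAI_CONTRA"), 26L)
  expect_equal(sum(meta$group == "HEALTHY"), 46L)
  # a CAI subject contributes opposite sides for the two groups
  for (sid in unique(meta$subject_id[meta$group == "CAI"])) {
    rows <- meta[meta$subject_id == sid, ]
    expect_equal(nrow(rows), 2L)
    expect_setequal(rows$side, c("L", "R"))
  }
  # unilateral healthy controls contribute single left ankles
  perHealthy <- table(meta$subject_id[meta$group == "HEALTHY"])
  expect_equal(sum(perHealthy == 2L), 20L)
  expect_equal(sum(perHealthy == 1L), 6L)
  expect_true(all(meta$gender %in% c("M", "F")))
  expect_true(all(meta$age >= 18 & meta$age <= 55))
  expect_equal(length(cohort$meshes), 98L)
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- generatorConfig(nCai = 3L, nHealthy = 3L, nBilateralHealthy = 2L,
    templateSubdiv = 2L, seed = 17L
  )
  c1 <- sampleCohort(cfg)
  c2 <- sampleCohort(cfg)
  expect_identical(c1$metadata, c2$metadata)
  for (i in seq_along(c1$meshes)) {
    expect_identical(vertices(c1$meshes[[i]]), vertices(c2$meshes[[i]]))
  }
  expect_identical(
    c1$groundTruth$instances[[5]]$latent,
    c2$groundTruth$instances[[5]]$latent
  )
})

test_that("latent coordinate variances match the configured spectrum", {
  # many instances; variance estimates should sit within 15% of the
  # planted spectrum
  cfg <- generatorConfig(
    nCai = 125L, nHealthy = 125L, nBilateralHealthy = 125L,
    templateSubdiv = 1L, effectSize = 0, seed = 23L
  )
  gt <- sampleCohort(cfg)$groundTruth
  z <- do.call(rbind, lapply(gt$instances, function(g) g$latent))
  expect_gte(nrow(z), 500L)
  v <- apply(z, 2L, var)
  expect_true(all(abs(v - cfg@spectrum) / cfg@spectrum < 0.15))
})

test_that("the planted group effect appears on the configured latent mode", {
  cfg <- generatorConfig(
    nCai = 60L, nHealthy = 60L, nBilateralHealthy = 60L,
    templateSubdiv = 1L, effectSize = 1.5, effectMode = 2L,
    contraFraction = 0.5, seed = 29L
  )
  cohort <- sampleCohort(cfg)
  z <- do.call(rbind, lapply(cohort$groundTruth$instances, function(g) g$latent))
  grp <- cohort$metadata$group
  sdM <- sqrt(cfg@spectrum[2])
  dCai <- (mean(z[grp == "CAI", 2]) - mean(z[grp == "HEALTHY", 2])) / sdM
  dContra <- (mean(z[grp == "CAI_CONTRA", 2]) - mean(z[grp == "HEALTHY", 2])) / sdM
  expect_equal(dCai, 1.5, tolerance = 0.35)
  expect_equal(dContra, 0.75, tolerance = 0.35)
  # no offset on the other modes
  d1 <- (mean(z[grp == "CAI", 1]) - mean(z[grp == "HEALTHY", 1])) / sqrt(cfg@spectrum[1])
  expect_lt(abs(d1), 0.35)
})

test_that("right-side instances are mirrored before the pose transform", {
  cfg <- generatorConfig(nCai = 2L, nHealthy = 2L, nBilateralHealthy = 2L,
    templateSubdiv = 1L, noiseSd = 0, rotMaxDeg = 0, transMax = 0,
    scaleRange = c(1, 1), seed = 31L
  )
  cohort <- sampleCohort(cfg)
  meta <- cohort$metadata
  gt <- cohort$groundTruth
  iR <- which(meta$side == "R")[1]
  expect_true(gt$instances[[iR]]$mirrored)
  iL <- which(meta$side == "L")[1]
  expect_false(gt$instances[[iL]]$mirrored)
})

test_that("cohorts serialise to PLY + CSV + JSON on disk", {
  cfg <- generatorConfig(nCai = 2L, nHealthy = 1L, nBilateralHealthy = 0L,
    templateSubdiv = 1L, seed = 37L
  )
  cohort <- sampleCohort(cfg)
  d <- file.path(tempdir(), "cohortOut")
  writeCohort(cohort, d)
  expect_true(file.exists(file.path(d, "metadata.csv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  plys <- list.files(d, pattern = "\\.ply$")
  expect_equal(length(plys), nrow(cohort$metadata))
  back <- readMesh(file.path(d, plys[1]))
  expect_equal(nrow(vertices(back)), nrow(vertices(cohort$meshes[[1]])))
})
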