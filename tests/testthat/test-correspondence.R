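# a small registered cohort built from near-identical clouds
makeAlignedFixture <- function(nClouds = 3L, nPts = 300L, perturb = 0,
                               seed = 60L) {
  tmpl <- boneTemplate(subdiv = 2L)
  base <- sampleSurface(tmpl, nPts, seed = seed)
  clouds <- lapply(seq_len(nClouds), function(i) {
    p <- points3d(base)
    if (perturb > 0 && i > 1) {
      # smooth low-frequency displacement, bounded by `perturb` (mm here;
      # clouds are normalised afterwards)
      p <- p + perturb * cbind(
        sin(p[, 2] / 10), cos(p[, 3] / 10), sin(p[, 1] / 10)
      ) / sqrt(3)
    }
    centerAndScale(pointCloud(p,
      normals = normals(base),
      instanceId = sprintf("inst%d", i)
    ))
  })
  suppressWarnings(groupwiseRegister(
    clouds,
    registrationParams(sigma = 3, nMean = 200L, maxIters = 30L),
    seed = seed
  ))
}

test_that("identical instances are corresponded identically", {
  reg <- makeAlignedFixture(nClouds = 3L)
  cm <- establishCorrespondence(reg, 150L, seed = 1, force = TRUE)
  expect_equal(ncol(cm@data), 3L * 150L)
  expect_equal(cm@data[1, ], cm@data[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cm@data[1, ], cm@data[3, ], tolerance = 1e-12, ignore_attr = TRUE)
  q <- correspondenceQuality(cm)
  expect_equal(q$max, 0, tolerance = 1e-9)
  expect_equal(q$mean, 0, tolerance = 1e-9)
  expect_length(q$perPoint, 150L)
})

test_that("a small smooth perturbation yields small corresponded distances", {
  # displacement magnitude 0.01 expressed on the normalised (unit
  # centroid size) scale of ~300-point clouds
  tmpl <- boneTemplate(subdiv = 3L)
  base <- sampleSurface(tmpl, 1000, seed = 61)
  A <- centerAndScale(base)
  p <- points3d(A)
  disp <- cbind(sin(40 * p[, 2]), cos(40 * p[, 3]), sin(40 * p[, 1]))
  disp <- 0.01 * disp / max(sqrt(rowSums(disp^2)))
  B <- pointCloud(points3d(A) + disp,
    normals = normals(A),
    centroidSize = centroidSize(A), instanceId = "B"
  )
  B <- centerAndScale(B)
  # mean cloud at the instances' own size keeps the aligned clouds on
  # the unit-size scale the distances are stated in
  reg <- suppressWarnings(groupwiseRegister(
    list(A, B), registrationParams(sigma = 3, nMean = 1000L, maxIters = 30L),
    seed = 62
  ))
  cm <- establishCorrespondence(reg, 250L, seed = 2, force = TRUE)
  q <- correspondenceQuality(cm)
  expect_lte(q$mean, 0.02)
})

test_that("correspondence enforces one-to-one matching across normal weights", {
  reg <- makeAlignedFixture(nClouds = 2L, perturb = 0.3)
  for (w in c(0, 0.1, 1, 10)) {
    cm <- establishCorrespondence(reg, 120L, normalWeight = w, seed = 3, force = TRUE)
    # one-to-one: each matched instance point used once, so the 120
    # corresponded points of an instance are 120 distinct points
    pts <- matrix(cm@data[2, ], ncol = 3L, byrow = TRUE)
    expect_equal(nrow(unique(pts)), 120L)
  }
})

test_that("correspondence width matches 3 x nPoints and errors are contracted", {
  reg <- makeAlignedFixture(nClouds = 2L)
  cm <- establishCorrespondence(reg, 100L, seed = 4, force = TRUE)
  expect_equal(dim(cm@data), c(2L, 300L))
  expect_equal(pointCount(cm), 100L)
  # requesting more points than an instance has
  expect_error(
    establishCorrespondence(reg, 10000L, seed = 4, force = TRUE),
    "at least nPoints"
  )
  # quality needs at least two instances
  one <- new("CorrespondenceMatrix",
    data = cm@data[1, , drop = FALSE], pointCount = 100L,
    instanceIds = "a", templateId = "mean"
  )
  expect_error(correspondenceQuality(one), "at least 2")
})

test_that("the template can be upsampled beyond the mean cloud", {
  reg <- makeAlignedFixture(nClouds = 2L, nPts = 400L)
  # mean cloud has 200 points; ask for more corresponded points
  cm <- establishCorrespondence(reg, 300L, seed = 5, force = TRUE)
  expect_equal(ncol(cm@data), 900L)
  pts <- matrix(cm@data[1, ], ncol = 3L, byrow = TRUE)
  expect_equal(nrow(unique(pts)), 300L)
})

test_that("correspondence matrices round-trip through CSV + JSON", {
  reg <- makeAlignedFixture(nClouds = 2L)
  cm <- establishCorrespondence(reg, 80L, seed = 6, force = TRUE)
  p <- file.path(tempdir(), "corr.csv")
  writeCorrespondence(cm, p)
  back <- readCorrespondence(p)
  expect_equal(back@data, cm@data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@pointCount, cm@pointCount)
  expect_equal(back@instanceIds, cm@instanceIds)
})
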