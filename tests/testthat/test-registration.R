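test_that("similarity transforms apply, compose and invert correctly", {
  cl <- pointCloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  idt <- similarityTransform()
  expect_identical(points3d(applyTransform(cl, idt)), points3d(cl))

  tr <- similarityTransform(translation = c(1, 0, 0))
  expect_equal(points3d(applyTransform(cl, tr))[1, ], c(1, 0, 0))

  set.seed(4)
  for (i in 1:5) {
    t1 <- similarityTransform(
      rotationMatrix(rnorm(3), runif(1, 0, 180)), rnorm(3), runif(1, 0.5, 2)
    )
    p <- matrix(rnorm(30), ncol = 3)
    fix <- pointCloud(p)
    round <- applyTransform(applyTransform(fix, t1), invertTransform(t1))
    expect_equal(points3d(round), p, tolerance = 1e-9)
    comp <- composeTransforms(invertTransform(t1), t1)
    expect_equal(comp@rotation, diag(3), tolerance = 1e-9)
    expect_equal(comp@translation, c(0, 0, 0), tolerance = 1e-9)
    expect_equal(comp@scale, 1, tolerance = 1e-12)
  }

  refl <- diag(c(-1, 1, 1))
  expect_error(
    applyTransform(cl, new("SimilarityTransform",
      rotation = refl, translation = c(0, 0, 0), scale = 1
    )),
    "mirrorSagittal"
  )
})

test_that("self-registration of identical clouds gives identity transforms", {
  cl <- centerAndScale(sampleSurface(boneTemplate(subdiv = 2L), 200, seed = 5))
  cl2 <- pointCloud(points3d(cl),
    normals = normals(cl),
    centroidSize = centroidSize(cl), instanceId = "copy"
  )
  # mean cloud at the instances' own size so the scale has no count
  # mismatch to absorb; a small fixed kernel makes the matching
  # point-to-point from the start, whose exact fixed point is the
  # identity
  reg <- groupwiseRegister(list(cl, cl2),
    registrationParams(
      sigma = 0.05, annealSigma = FALSE, nMean = 200L, maxIters = 30L
    ),
    seed = 1
  )
  for (tr in transforms(reg)) {
    expect_equal(tr@rotation, diag(3), tolerance = 1e-6)
    expect_equal(tr@scale, 1, tolerance = 1e-6)
    expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-6)
  }
  # the mean lies on the common shape
  expect_lt(nnRMSD(points3d(meanCloud(reg)), points3d(cl)), 1e-3)
})

test_that("a known similarity perturbation is recovered", {
  tmpl <- boneTemplate(subdiv = 3L)
  clA <- sampleSurface(tmpl, 400, seed = 21)
  R <- rotationMatrix(c(0.3, -1, 0.5), 25)
  pB <- sweep(1.1 * points3d(clA) %*% t(R), 2, c(4, -2, 7), "+")
  clB <- pointCloud(pB, normals = normals(clA) %*% t(R), instanceId = "B")
  A <- centerAndScale(clA)
  B <- centerAndScale(clB)
  reg <- suppressWarnings(groupwiseRegister(
    list(A, B),
    registrationParams(sigma = 3, nMean = 200L, maxIters = 60L),
    seed = 2
  ))
  # estimated relative rotation between the two aligned poses
  Rrel <- t(transforms(reg)[[2]]@rotation) %*% transforms(reg)[[1]]@rotation
  ang <- acos(pmin(1, (sum(diag(Rrel)) - 1) / 2)) * 180 / pi
  expect_equal(ang, 25, tolerance = 0.5)
  expect_lt(pairRMSD(points3d(reg@clouds[[1]]), points3d(reg@clouds[[2]])), 1e-3)
})

test_that("the registered mean cloud is unbiased: centroid 0, unit size", {
  tmpl <- boneTemplate(subdiv = 2L)
  clouds <- lapply(1:4, function(i) {
    centerAndScale(sampleSurface(tmpl, 250, seed = 30 + i))
  })
  reg <- suppressWarnings(groupwiseRegister(
    clouds, registrationParams(sigma = 3, nMean = 150L, maxIters = 40L),
    seed = 3
  ))
  M <- points3d(meanCloud(reg))
  expect_equal(colMeans(M), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(sqrt(sum(sweep(M, 2, colMeans(M))^2)), 1, tolerance = 1e-6)
  expect_equal(length(reg@clouds), length(transforms(reg)))
  for (tr in transforms(reg)) {
    expect_equal(crossprod(tr@rotation), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(det(tr@rotation), 1, tolerance = 1e-6)
  }
})

test_that("permuting the instance order barely changes the mean cloud", {
  tmpl <- boneTemplate(subdiv = 2L)
  clouds <- lapply(1:4, function(i) {
    centerAndScale(sampleSurface(tmpl, 250, seed = 40 + i))
  })
  par <- registrationParams(sigma = 3, nMean = 150L, maxIters = 40L)
  r1 <- suppressWarnings(groupwiseRegister(clouds, par, seed = 5))
  r2 <- suppressWarnings(groupwiseRegister(clouds[c(2, 3, 4, 1)], par, seed = 5))
  expect_lt(nnRMSD(points3d(meanCloud(r1)), points3d(meanCloud(r2))), 1e-2)
})

test_that("the inner EM objective is non-decreasing", {
  tmpl <- boneTemplate(subdiv = 2L)
  cl <- centerAndScale(sampleSurface(tmpl, 300, seed = 50))
  M <- points3d(centerAndScale(sampleSurface(tmpl, 200, seed = 51)))
  par <- registrationParams(sigma = 3, nMean = 200L, innerIters = 15L, innerTol = 1e-12)
  fit <- tarsalSSM:::cpdSimilarity(
    points3d(cl), M, (3 / centroidSize(cl))^2, par,
    sigma2Floor = 1e-8
  )
  tr <- fit$llTrace
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-1])))
})

test_that("invalid inputs and non-convergence are handled as contracted", {
  cl <- sampleSurface(boneTemplate(subdiv = 1L), 100, seed = 6) # not normalised
  expect_error(
    groupwiseRegister(list(cl, cl), registrationParams(nMean = 50L)),
    "not normalized"
  )
  a <- centerAndScale(sampleSurface(boneTemplate(subdiv = 2L), 150, seed = 7))
  b <- centerAndScale(sampleSurface(boneTemplate(subdiv = 2L), 150, seed = 8))
  expect_warning(
    reg <- groupwiseRegister(
      list(a, b),
      registrationParams(nMean = 100L, maxIters = 2L, tol = 1e-12, tolAligned = 1e-12),
      seed = 1
    ),
    "did not converge"
  )
  expect_false(reg@converged)
  expect_equal(reg@iterationsRun, 2L)
  expect_error(groupwiseRegister(list(a), registrationParams(nMean = 50L)), "at least 2")
})

test_that("registration parameters echo the published bone settings", {
  talus <- registrationParams(sigma = 3, nMean = 2000L, lambda = 1e-6)
  calcaneus <- registrationParams(sigma = 3, nMean = 2000L, lambda = 5e-4)
  expect_equal(talus@sigma, 3)
  expect_equal(talus@nMean, 2000L)
  expect_equal(talus@lambda, 1e-6)
  expect_equal(calcaneus@lambda, 5e-4)
  # and they are carried into the run log / cohort object
  a <- centerAndScale(sampleSurface(boneTemplate(subdiv = 1L), 80, seed = 9))
  b <- centerAndScale(sampleSurface(boneTemplate(subdiv = 1L), 80, seed = 10))
  reg <- suppressWarnings(groupwiseRegister(
    list(a, b), registrationParams(sigma = 3, nMean = 60L, lambda = 1e-6, maxIters = 10L),
    seed = 1
  ))
  expect_equal(reg@params@sigma, 3)
  expect_equal(reg@params@lambda, 1e-6)
  expect_true(all(c("iteration", "meanChange", "logLik") %in% names(reg@log)))
})
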