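test_that("PCA matches brute-force covariance eigendecomposition", {
  set.seed(101)
  for (rep in 1:20) {
    X <- matrix(rnorm(5 * 12), nrow = 5)
    model <- buildSSM(X)
    C <- cov(X)
    eig <- eigen(C, symmetric = TRUE)
    kept <- seq_along(eigenvalues(model))
    expect_equal(eigenvalues(model), eig$values[kept], tolerance = 1e-8)
    for (j in kept) {
      # eigenvectors agree up to sign
      expect_equal(abs(sum(modes(model)[, j] * eig$vectors[, j])), 1,
        tolerance = 1e-8
      )
    }
    expect_equal(sum(eigenvalues(model)), sum(diag(C)), tolerance = 1e-8)
  }
})

test_that("rank-1 and degenerate cohorts are handled as contracted", {
  v <- rnorm(12)
  v <- v / sqrt(sum(v^2))
  xbar <- rnorm(12)
  X <- rbind(xbar + 0.5 * v, xbar, xbar - 0.5 * v)
  model <- buildSSM(X)
  expect_equal(length(eigenvalues(model)), 1L)
  expect_equal(abs(sum(modes(model)[, 1] * v)), 1, tolerance = 1e-8)

  expect_warning(z <- buildSSM(matrix(1, 4, 12)), "zero modes")
  expect_equal(ncol(modes(z)), 0L)
})

test_that("variance fractions are exact and mode retention uses strict >", {
  mk <- function(ev) {
    k <- length(ev)
    Q <- qr.Q(qr(matrix(rnorm(3 * k * k), 3 * k, k)))
    new("ShapeModel",
      meanShape = numeric(3 * k), modes = Q, eigenvalues = ev,
      retained = k, pointCount = as.integer(k)
    )
  }
  expect_equal(varianceExplained(mk(c(3, 1))), c(0.75, 0.25))
  expect_equal(varianceExplained(mk(5)), 1)
  expect_equal(sum(varianceExplained(mk(c(9, 5, 3, 2, 1)))), 1, tolerance = 1e-12)

  # fractions (0.30, 0.20, 0.06, 0.05, 0.04, then 35 x 0.01):
  # 0.06 is retained, 0.05 is not (> is strict)
  m <- mk(c(0.30, 0.20, 0.06, 0.05, 0.04, rep(0.01, 35)))
  expect_equal(sum(varianceExplained(m)), 1, tolerance = 1e-12)
  expect_equal(selectModes(m, 0.05), 3L)
  # floor: at least mode 1 even when nothing clears the threshold
  expect_equal(selectModes(mk(c(0.9, 0.1) * 2), 0.95), 1L)
  expect_error(selectModes(m, 1.2), "threshold")
})

test_that("projection and reconstruction satisfy the model identities", {
  set.seed(102)
  X <- matrix(rnorm(8 * 15), nrow = 8)
  model <- buildSSM(X)
  nm <- length(eigenvalues(model))

  expect_equal(projectShape(meanShape(model), model, nModes = nm),
    numeric(nm),
    tolerance = 1e-10
  )
  b1 <- projectShape(meanShape(model) + 2 * modes(model)[, 1], model, nModes = nm)
  expect_equal(b1, c(2, numeric(nm - 1)), tolerance = 1e-8)

  # reconstruct(project(x)) = x on the training span, all modes
  for (i in 1:4) {
    b <- projectShape(X[i, ], model, nModes = nm)
    expect_equal(reconstructShape(model, b, c = nm), X[i, ], tolerance = 1e-8)
  }

  # b matches a generic least-squares fit of the linear model
  b <- projectShape(X[5, ], model, nModes = nm)
  ls <- qr.solve(modes(model), X[5, ] - meanShape(model))
  expect_equal(b, ls, tolerance = 1e-8)

  # +/- 2 SD along a mode are symmetric about the mean
  up <- reconstructShape(model, c(0, 2 * sqrt(eigenvalues(model)[2])), c = 2)
  dn <- reconstructShape(model, c(0, -2 * sqrt(eigenvalues(model)[2])), c = 2)
  expect_equal(
    sqrt(sum((up - meanShape(model))^2)),
    sqrt(sum((dn - meanShape(model))^2)),
    tolerance = 1e-10
  )
  expect_equal(up + dn, 2 * meanShape(model), tolerance = 1e-10)

  expect_equal(reconstructShape(model, numeric(nm), c = nm), meanShape(model))
  expect_error(projectShape(numeric(5), model), "does not match")
  retainedModes(model) <- 2L
  expect_error(reconstructShape(model, rnorm(nm), c = nm), "exceeds")
})

test_that("truncation residual equals the sum of dropped eigenvalues", {
  set.seed(103)
  X <- matrix(rnorm(12 * 30), nrow = 12)
  model <- buildSSM(X)
  nm <- length(eigenvalues(model))
  for (c in c(2L, 5L, nm)) {
    resid <- vapply(seq_len(nrow(X)), function(i) {
      b <- projectShape(X[i, ], model, nModes = nm)
      sum((X[i, ] - reconstructShape(model, b, c = c))^2)
    }, numeric(1))
    # mean squared residual = sum of dropped eigenvalues (n-1 divisor)
    expect_equal(sum(resid) / (nrow(X) - 1),
      sum(eigenvalues(model)[seq_len(nm) > c]),
      tolerance = 1e-6
    )
  }
})

test_that("shape parameters are centred with variances equal to eigenvalues", {
  set.seed(104)
  X <- matrix(rnorm(10 * 24, sd = 2), nrow = 10)
  model <- buildSSM(X)
  sp <- shapeParameters(model, X, nModes = length(eigenvalues(model)))
  expect_equal(colMeans(sp@b), numeric(ncol(sp@b)),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  expect_equal(apply(sp@b, 2, var), eigenvalues(model), tolerance = 1e-6,
    ignore_attr = TRUE
  )
  expect_equal(apply(sp@normalizedB, 2, var), rep(1, ncol(sp@b)),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})

test_that("the fitted model is deterministic, with pinned mode signs", {
  set.seed(105)
  X <- matrix(rnorm(7 * 18), nrow = 7)
  m1 <- buildSSM(X)
  m2 <- buildSSM(X)
  expect_identical(modes(m1), modes(m2))
  for (j in seq_len(ncol(modes(m1)))) {
    col <- modes(m1)[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("shape models round-trip through the on-disk archive", {
  set.seed(106)
  X <- matrix(rnorm(6 * 12), nrow = 6)
  model <- buildSSM(X, threshold = 0.05)
  d <- file.path(tempdir(), "modelArchive")
  writeShapeModel(model, d)
  back <- readShapeModel(d)
  expect_equal(meanShape(back), meanShape(model), tolerance = 1e-12)
  expect_equal(modes(back), modes(model), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(eigenvalues(back), eigenvalues(model), tolerance = 1e-12)
  expect_equal(retainedModes(back), retainedModes(model))
})
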