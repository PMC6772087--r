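#' @useDynLib tarsalSSM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats anova lm oneway.test pairwise.t.test pf pnorm pt rnorm
#'   runif sd var prcomp cor setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

#' SurfaceMesh: a triangulated closed bone surface
#'
#' Holds one bone instance as a triangulated surface: vertex coordinates
#' (millimetres), triangle faces as 1-based vertex-index triples, and
#' per-vertex outward unit normals.
#'
#' @slot vertices numeric matrix, vertices x 3, coordinates in mm.
#' @slot faces integer matrix, faces x 3, 1-based vertex indices.
#' @slot normals numeric matrix, vertices x 3, unit outward normals.
#' @slot instanceId character scalar, opaque instance label.
#'
#' @seealso [readMesh()], [surfaceMesh()], [mirrorSagittal()],
#'   [sampleSurface()]
#' @export
setClass("SurfaceMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    normals = "matrix",
    instanceId = "character"
  )
)

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  n <- object@normals
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 3L) msg <- c(msg, "vertices must be a numeric matrix with 3 columns")
  if (ncol(f) != 3L) msg <- c(msg, "faces must have 3 columns")
  if (nrow(v) < 4L) msg <- c(msg, "mesh must have at least 4 vertices")
  if (nrow(f) < 4L) msg <- c(msg, "mesh must have at least 4 faces")
  if (length(msg) == 0L) {
    if (any(f < 1L) || any(f > nrow(v))) {
      msg <- c(msg, "face indices must refer to existing vertices")
    }
    if (any(!is.finite(v))) msg <- c(msg, "vertex coordinates must be finite")
    if (nrow(n) != nrow(v) || ncol(n) != 3L) {
      msg <- c(msg, "normals must be a vertices x 3 matrix")
    } else {
      len <- sqrt(rowSums(n^2))
      if (any(abs(len - 1) > 1e-6)) {
        msg <- c(msg, "normals must have unit length (tolerance 1e-6)")
      }
    }
  }
  if (length(object@instanceId) != 1L) msg <- c(msg, "instanceId must be a single string")
  if (length(msg)) msg else TRUE
})

#' PointCloud: points sampled across a bone surface
#'
#' A set of surface points with optional per-point unit normals. Before
#' normalisation coordinates are in millimetres; after [centerAndScale()]
#' they are dimensionless (unit centroid size) and `centroidSize` records
#' the original size.
#'
#' @slot points numeric matrix, points x 3.
#' @slot normals numeric matrix, points x 3 (or 0 x 3 when absent).
#' @slot centroidSize numeric scalar; the centroid size recorded at
#'   normalisation (`NA` before normalisation).
#' @slot instanceId character scalar.
#'
#' @seealso [sampleSurface()], [centerAndScale()]
#' @export
setClass("PointCloud",
  representation(
    points = "matrix",
    normals = "matrix",
    centroidSize = "numeric",
    instanceId = "character"
  )
)

setValidity("PointCloud", function(object) {
  p <- object@points
  n <- object@normals
  msg <- character()
  if (!is.numeric(p) || ncol(p) != 3L) msg <- c(msg, "points must be a numeric matrix with 3 columns")
  if (nrow(p) < 1L) msg <- c(msg, "point cloud must contain at least one point")
  if (any(!is.finite(p))) msg <- c(msg, "point coordinates must be finite")
  if (nrow(n) > 0L) {
    if (nrow(n) != nrow(p) || ncol(n) != 3L) {
      msg <- c(msg, "normals, when present, must be a points x 3 matrix")
    } else if (any(abs(sqrt(rowSums(n^2)) - 1) > 1e-6)) {
      msg <- c(msg, "normals must have unit length (tolerance 1e-6)")
    }
  }
  cs <- object@centroidSize
  if (length(cs) != 1L) {
    msg <- c(msg, "centroidSize must be a single numeric")
  } else if (!is.na(cs) && cs <= 0) {
    msg <- c(msg, "centroidSize must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' SimilarityTransform: rotation, translation and isotropic scale
#'
#' Maps a point p to `scale * R %*% p + translation`. Rotations are proper
#' (determinant +1); mirroring is deliberately excluded and must go through
#' [mirrorSagittal()].
#'
#' @slot rotation 3 x 3 orthogonal matrix with determinant +1.
#' @slot translation length-3 numeric vector.
#' @slot scale positive numeric scalar.
#'
#' @seealso [similarityTransform()], [applyTransform()]
#' @export
setClass("SimilarityTransform",
  representation(rotation = "matrix", translation = "numeric", scale = "numeric")
)

setValidity("SimilarityTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) msg <- c(msg, "rotation must be orthogonal (tolerance 1e-6)")
    if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "rotation must be proper (det +1); mirroring must go through mirrorSagittal()")
  }
  if (length(object@translation) != 3L) msg <- c(msg, "translation must have length 3")
  if (length(object@scale) != 1L || object@scale <= 0) msg <- c(msg, "scale must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' RegistrationParams: groupwise registration settings
#'
#' @slot sigma Gaussian kernel width in mm (pre-normalisation units); it is
#'   divided by each instance's recorded centroid size, so the printed
#'   value keeps its physical meaning on unit-size clouds. Used as the
#'   initial width; see `annealSigma`.
#' @slot nMean number of points in the evolving mean cloud.
#' @slot lambda dimensionless trade-off stiffening the mean update towards
#'   its previous configuration (larger = stiffer mean).
#' @slot maxIters maximum outer (mean-update) iterations.
#' @slot tol convergence tolerance on the relative Frobenius change of the
#'   mean cloud.
#' @slot tolAligned secondary convergence tolerance: RMS per-point motion
#'   of the aligned clouds between consecutive outer iterations. The mean
#'   cloud keeps diffusing tangentially along the surface long after the
#'   aligned poses are stable, so pose stability is accepted as
#'   convergence too.
#' @slot wOutlier uniform-outlier mixture weight (robustness constant).
#' @slot innerIters maximum EM iterations per instance per outer iteration.
#' @slot innerTol relative log-likelihood tolerance of the inner EM.
#' @slot annealSigma logical; when TRUE (default) the kernel width is
#'   re-estimated by the EM closed form each inner iteration, starting from
#'   `sigma`; when FALSE it stays fixed at `sigma`.
#' @slot sigmaFloorFactor lower bound on the annealed kernel width,
#'   expressed as a fraction of the mean cloud's median nearest-neighbour
#'   spacing; keeps responsibilities soft so the mean update remains a
#'   stable contraction.
#'
#' @seealso [registrationParams()], [groupwiseRegister()]
#' @export
setClass("RegistrationParams",
  representation(
    sigma = "numeric", nMean = "integer", lambda = "numeric",
    maxIters = "integer", tol = "numeric", tolAligned = "numeric",
    wOutlier = "numeric",
    innerIters = "integer", innerTol = "numeric", annealSigma = "logical",
    sigmaFloorFactor = "numeric"
  )
)

setValidity("RegistrationParams", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@nMean < 4L) msg <- c(msg, "nMean must be >= 4")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@maxIters < 1L) msg <- c(msg, "maxIters must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (object@tolAligned <= 0) msg <- c(msg, "tolAligned must be > 0")
  if (object@wOutlier < 0 || object@wOutlier >= 1) msg <- c(msg, "wOutlier must be in [0, 1)")
  if (object@sigmaFloorFactor < 0) msg <- c(msg, "sigmaFloorFactor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AlignedCohort: a registered set of bone point clouds
#'
#' Output of [groupwiseRegister()]: the aligned unit-size clouds, the
#' converged mean cloud, and the per-instance similarity transform mapping
#' each input cloud to its aligned pose.
#'
#' @slot clouds list of aligned [PointCloud-class] objects.
#' @slot meanCloud the evolving-mean [PointCloud-class] (unit centroid
#'   size, centroid at the origin).
#' @slot transforms list of [SimilarityTransform-class], one per instance.
#' @slot iterationsRun integer, outer iterations executed.
#' @slot converged logical.
#' @slot log data.frame run log: iteration, relative mean change, total
#'   GMM log-likelihood.
#' @slot params the [RegistrationParams-class] used.
#'
#' @export
setClass("AlignedCohort",
  representation(
    clouds = "list", meanCloud = "PointCloud", transforms = "list",
    iterationsRun = "integer", converged = "logical",
    log = "data.frame", params = "RegistrationParams"
  )
)

setValidity("AlignedCohort", function(object) {
  msg <- character()
  if (length(object@clouds) != length(object@transforms)) {
    msg <- c(msg, "clouds and transforms must have equal length")
  }
  ok <- vapply(object@transforms, function(t) is(t, "SimilarityTransform"), logical(1))
  if (!all(ok)) msg <- c(msg, "transforms must all be SimilarityTransform objects")
  if (length(msg)) msg else TRUE
})

#' CorrespondenceMatrix: corresponded coordinates across all instances
#'
#' Row i holds the ordered (x, y, z) coordinates of instance i's N
#' corresponded surface points; columns are (x1, y1, z1, x2, ...). Point
#' order is identical across instances, so the matrix feeds PCA directly.
#'
#' @slot data numeric matrix, instances x 3N.
#' @slot pointCount integer N.
#' @slot instanceIds character vector of row labels.
#' @slot templateId label of the template the correspondence was built on.
#'
#' @seealso [establishCorrespondence()], [buildSSM()]
#' @export
setClass("CorrespondenceMatrix",
  representation(
    data = "matrix", pointCount = "integer",
    instanceIds = "character", templateId = "character"
  )
)

setValidity("CorrespondenceMatrix", function(object) {
  msg <- character()
  if (ncol(object@data) != 3L * object@pointCount) {
    msg <- c(msg, "data must have 3 * pointCount columns")
  }
  if (any(!is.finite(object@data))) msg <- c(msg, "all entries must be finite")
  if (nrow(object@data) != length(object@instanceIds)) {
    msg <- c(msg, "instanceIds must match the number of rows")
  }
  if (length(msg)) msg else TRUE
})

#' ShapeModel: a PCA point-distribution model
#'
#' The linear shape model x = xbar + sum_s b_s * Phi_s: mean shape, an
#' orthonormal matrix of modes of shape variation, their variances
#' (eigenvalues of the sample covariance), and the number of retained
#' modes.
#'
#' @slot meanShape numeric vector of length 3N.
#' @slot modes numeric matrix 3N x m, orthonormal columns.
#' @slot eigenvalues nonincreasing nonnegative numeric vector of length m.
#' @slot retained integer, number of modes used by default in projections
#'   and reconstructions.
#' @slot pointCount integer N.
#'
#' @seealso [buildSSM()], [selectModes()], [projectShape()],
#'   [reconstructShape()]
#' @export
setClass("ShapeModel",
  representation(
    meanShape = "numeric", modes = "matrix", eigenvalues = "numeric",
    retained = "integer", pointCount = "integer"
  )
)

setValidity("ShapeModel", function(object) {
  msg <- character()
  m <- ncol(object@modes)
  if (length(object@eigenvalues) != m) msg <- c(msg, "one eigenvalue per mode required")
  if (m > 0L) {
    if (nrow(object@modes) != length(object@meanShape)) {
      msg <- c(msg, "modes must have length(meanShape) rows")
    } else if (max(abs(crossprod(object@modes) - diag(m))) > 1e-8) {
      msg <- c(msg, "modes must be orthonormal (tolerance 1e-8)")
    }
    if (is.unsorted(rev(object@eigenvalues))) msg <- c(msg, "eigenvalues must be nonincreasing")
    if (any(object@eigenvalues < 0)) msg <- c(msg, "eigenvalues must be nonnegative")
    if (object@retained < 1L || object@retained > m) {
      msg <- c(msg, "retained must be between 1 and the number of modes")
    }
  }
  if (length(object@meanShape) != 3L * object@pointCount) {
    msg <- c(msg, "meanShape must have length 3 * pointCount")
  }
  if (length(msg)) msg else TRUE
})

#' ShapeParameters: per-instance mode coefficients
#'
#' @slot b numeric matrix, instances x retained, raw shape parameters.
#' @slot normalizedB the same divided per mode by sqrt(eigenvalue), i.e.
#'   in standard-deviation units.
#'
#' @seealso [shapeParameters()]
#' @export
setClass("ShapeParameters",
  representation(b = "matrix", normalizedB = "matrix")
)

#' ComparisonResult: mode-wise three-group statistics
#'
#' @slot results tidy data.frame with columns mode, test, comparison,
#'   p_raw, p_adjusted, significant.
#' @slot modeSummary per-mode data.frame: KS normality p, omnibus ANOVA p,
#'   ANCOVA group-effect p, and a flagged-comparisons string.
#' @slot alpha the significance level used.
#' @slot ancovaChanged logical: did covariate adjustment change any
#'   omnibus significance flag?
#'
#' @seealso [runComparison()]
#' @export
setClass("ComparisonResult",
  representation(
    results = "data.frame", modeSummary = "data.frame",
    alpha = "numeric", ancovaChanged = "logical"
  )
)

#' GeneratorConfig: settings of the synthetic bone-cohort generator
#'
#' Describes a virtual study population: a superellipsoid-with-bumps
#' template bone, k orthonormal smooth latent deformation modes with a
#' declining variance spectrum, a group mean offset planted on one mode,
#' random similarity transforms and left/right mirroring, per-vertex
#' surface noise, and the subject structure (unilateral CAI patients
#' contributing an ipsilateral and a contralateral instance, healthy
#' controls with one or both sides).
#'
#' @slot nCai number of unilateral CAI subjects (two instances each).
#' @slot nHealthy number of healthy subjects.
#' @slot nBilateralHealthy healthy subjects contributing both sides.
#' @slot templateSubdiv icosphere subdivision level of the template mesh.
#' @slot semiAxes superellipsoid semi-axes (mm).
#' @slot exponent superellipsoid exponent p in |x/a|^p + |y/b|^p + |z/c|^p = 1.
#' @slot nBumps,bumpAmp,bumpWidth smooth radial bumps approximating a
#'   tarsal-bone-like blob.
#' @slot latentModes number k of orthonormal latent deformation fields.
#' @slot spectrum strictly decreasing latent variances (mm^2).
#' @slot effectMode index of the mode carrying the group difference.
#' @slot effectSize group mean offset in SD units of that mode.
#' @slot contraFraction fraction of the effect given to contralateral
#'   instances (default 1: contralateral resembles ipsilateral).
#' @slot noiseSd per-vertex measurement noise SD (mm), applied along
#'   vertex normals.
#' @slot rotMaxDeg,transMax,scaleRange random similarity-transform bounds.
#' @slot ageRangeCai,ageRangeHealthy uniform age ranges (years).
#' @slot genderRatio probability of male.
#' @slot confoundAgeSlope optional age-to-effect-mode coupling
#'   (latent SD units per year).
#' @slot seed integer root seed.
#'
#' @seealso [generatorConfig()], [sampleCohort()]
#' @export
setClass("GeneratorConfig",
  representation(
    nCai = "integer", nHealthy = "integer", nBilateralHealthy = "integer",
    templateSubdiv = "integer", semiAxes = "numeric", exponent = "numeric",
    nBumps = "integer", bumpAmp = "numeric", bumpWidth = "numeric",
    latentModes = "integer", spectrum = "numeric", effectMode = "integer",
    effectSize = "numeric", contraFraction = "numeric", noiseSd = "numeric",
    rotMaxDeg = "numeric", transMax = "numeric", scaleRange = "numeric",
    ageRangeCai = "numeric", ageRangeHealthy = "numeric",
    genderRatio = "numeric", confoundAgeSlope = "numeric", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nCai < 0L || object@nHealthy < 0L) msg <- c(msg, "subject counts must be nonnegative")
  if (object@nBilateralHealthy > object@nHealthy) {
    msg <- c(msg, "nBilateralHealthy cannot exceed nHealthy")
  }
  k <- object@latentModes
  if (length(object@spectrum) != k) msg <- c(msg, "spectrum must have one variance per latent mode")
  if (k > 1L && any(diff(object@spectrum) >= 0)) msg <- c(msg, "spectrum must be strictly decreasing")
  if (any(object@spectrum <= 0)) msg <- c(msg, "spectrum variances must be positive")
  if (object@effectMode < 1L || object@effectMode > k) msg <- c(msg, "effectMode must index a latent mode")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@scaleRange) != 2L || any(object@scaleRange <= 0)) {
    msg <- c(msg, "scaleRange must be two positive bounds")
  }
  if (length(msg)) msg else TRUE
})
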