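#' Build the PCA statistical shape model
#'
#' Computes the point-distribution model x = xbar + sum_s b_s Phi_s: the
#' mean shape is the columnwise mean of the correspondence matrix, and the
#' modes of shape variation and their variances are the eigenvectors and
#' eigenvalues of the sample covariance (divisor n - 1). The decomposition
#' is obtained through the SVD of the centred data — exact and cheap on
#' the instances-sized problem, where the explicit 3N x 3N covariance
#' would be infeasible for dense bone correspondences. Eigenvector signs
#' are pinned (largest-magnitude entry positive) so b values are
#' reproducible across runs.
#'
#' @param x a [CorrespondenceMatrix-class] or a plain instances x 3N
#'   matrix, with at least 3 rows.
#' @param threshold optional variance fraction passed to [selectModes()]
#'   to set the retained-mode count; by default all modes are retained.
#' @return a [ShapeModel-class]. Rank-0 data (all rows identical) gives a
#'   model with zero modes and a warning.
#' @export
buildSSM <- function(x, threshold = NULL) {
  if (is(x, "CorrespondenceMatrix")) {
    N <- x@pointCount
    X <- x@data
  } else {
    X <- as.matrix(x)
    stopIf(ncol(X) %% 3L != 0L, "matrix width must be a multiple of 3")
    N <- ncol(X) %/% 3L
  }
  stopIf(nrow(X) < 3L, "need at least 3 instances")
  stopIf(any(!is.finite(X)), "all entries must be finite")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  n <- nrow(X)
  if (max(abs(Xc)) < 1e-12 * max(1, max(abs(xbar)))) {
    warning("all shapes identical: model has zero modes", call. = FALSE)
    model <- new("ShapeModel",
      meanShape = xbar, modes = matrix(numeric(0), ncol(X), 0L),
      eigenvalues = numeric(0), retained = 0L, pointCount = as.integer(N)
    )
    return(model)
  }
  sv <- svd(Xc, nu = 0L, nv = min(n - 1L, ncol(X)))
  ev <- sv$d[seq_len(ncol(sv$v))]^2 / (n - 1)
  ev[ev < 0] <- 0
  keep <- ev > max(ev) * 1e-12
  modes <- sv$v[, keep, drop = FALSE]
  ev <- ev[keep]
  # pin eigenvector signs: largest-magnitude entry positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  model <- new("ShapeModel",
    meanShape = xbar, modes = modes, eigenvalues = ev,
    retained = ncol(modes), pointCount = as.integer(N)
  )
  if (!is.null(threshold)) retainedModes(model) <- selectModes(model, threshold)
  model
}

#' @rdname accessors
#' @export
setMethod("meanShape", "ShapeModel", function(object) object@meanShape)
#' @rdname accessors
#' @export
setMethod("modes", "ShapeModel", function(object) object@modes)
#' @rdname accessors
#' @export
setMethod("eigenvalues", "ShapeModel", function(object) object@eigenvalues)
#' @rdname accessors
#' @export
setMethod("retainedModes", "ShapeModel", function(object) object@retained)
#' @rdname accessors
#' @export
setMethod("retainedModes<-", "ShapeModel", function(object, value) {
  object@retained <- as.integer(value)
  validObject(object)
  object
})
#' @rdname accessors
#' @export
setMethod("pointCount", "ShapeModel", function(object) object@pointCount)

setMethod("show", "ShapeModel", function(object) {
  m <- length(object@eigenvalues)
  cat(sprintf(
    "ShapeModel: %d points, %d modes (%d retained)\n",
    object@pointCount, m, object@retained
  ))
  if (m > 0L) {
    fr <- varianceExplained(object)
    k <- min(m, 5L)
    cat(sprintf(
      "  variance explained by first %d modes: %s\n", k,
      paste(sprintf("%.1f%%", 100 * fr[seq_len(k)]), collapse = ", ")
    ))
  }
})

#' Per-mode fractions of total shape variance
#'
#' @param model a [ShapeModel-class] with at least one mode.
#' @return nonincreasing vector of fractions summing to 1.
#' @examples
#' # eigenvalues (3, 1) -> fractions (0.75, 0.25)
#' @export
varianceExplained <- function(model) {
  stopIf(!is(model, "ShapeModel"), "model must be a ShapeModel")
  stopIf(length(model@eigenvalues) < 1L, "model has no modes")
  model@eigenvalues / sum(model@eigenvalues)
}

#' Count the modes to retain for statistics
#'
#' A mode is retained when it represents strictly more than `threshold`
#' of the total shape variance; at least the first mode is always
#' retained.
#'
#' @param model a [ShapeModel-class].
#' @param threshold variance fraction in (0, 1); default 0.05.
#' @return integer c >= 1.
#' @export
selectModes <- function(model, threshold = 0.05) {
  stopIf(threshold <= 0 || threshold >= 1, "threshold must be in (0, 1)")
  fr <- varianceExplained(model)
  max(1L, sum(fr > threshold))
}

#' Project a shape onto the model's modes
#'
#' Returns the shape parameters b_s = Phi_s' (x - xbar): how far the
#' shape sits from the mean along each mode of shape variation.
#'
#' @param shape numeric vector of length 3N.
#' @param model a [ShapeModel-class].
#' @param nModes number of leading modes (default the retained count).
#' @return numeric vector of length `nModes`.
#' @export
projectShape <- function(shape, model, nModes = retainedModes(model)) {
  stopIf(!is(model, "ShapeModel"), "model must be a ShapeModel")
  stopIf(length(shape) != length(model@meanShape),
    sprintf(
      "shape length %d does not match model dimension %d",
      length(shape), length(model@meanShape)
    )
  )
  nModes <- as.integer(nModes)
  stopIf(nModes < 1L || nModes > ncol(model@modes),
    "nModes must be between 1 and the number of model modes"
  )
  as.vector(crossprod(model@modes[, seq_len(nModes), drop = FALSE],
    shape - model@meanShape
  ))
}

#' Reconstruct a shape from mode coefficients
#'
#' Evaluates x = xbar + sum_{s <= c} b_s Phi_s.
#'
#' @param model a [ShapeModel-class].
#' @param b coefficient vector with length(b) >= c.
#' @param c number of modes to use (default all supplied coefficients);
#'   must not exceed the model's retained count.
#' @return shape vector of length 3N.
#' @export
reconstructShape <- function(model, b, c = length(b)) {
  stopIf(!is(model, "ShapeModel"), "model must be a ShapeModel")
  c <- as.integer(c)
  stopIf(c > model@retained,
    sprintf("c = %d exceeds the retained mode count %d", c, model@retained)
  )
  stopIf(length(b) < c, "length(b) must be at least c")
  if (c == 0L) return(model@meanShape)
  model@meanShape + as.vector(model@modes[, seq_len(c), drop = FALSE] %*% b[seq_len(c)])
}

#' Shape parameters of a training cohort
#'
#' Projects every instance of a correspondence matrix onto the model's
#' leading modes, returning both raw b values and SD-normalised values
#' b_s / sqrt(lambda_s) (the units used when quoting a subject as, say,
#' "+2.3 SD along a mode").
#'
#' @param model a [ShapeModel-class].
#' @param x a [CorrespondenceMatrix-class] or instances x 3N matrix.
#' @param nModes leading modes to use (default the retained count).
#' @return a [ShapeParameters-class].
#' @export
shapeParameters <- function(model, x, nModes = retainedModes(model)) {
  X <- if (is(x, "CorrespondenceMatrix")) x@data else as.matrix(x)
  stopIf(ncol(X) != length(model@meanShape), "matrix width does not match the model")
  nModes <- as.integer(nModes)
  Phi <- model@modes[, seq_len(nModes), drop = FALSE]
  b <- sweep(X, 2L, model@meanShape) %*% Phi
  sdv <- sqrt(model@eigenvalues[seq_len(nModes)])
  sdv[sdv < 1e-300] <- 1
  nb <- sweep(b, 2L, sdv, "/")
  colnames(b) <- colnames(nb) <- paste0("mode", seq_len(nModes))
  rownames(b) <- rownames(nb) <- rownames(X)
  new("ShapeParameters", b = b, normalizedB = nb)
}

#' Serialise / restore a shape model
#'
#' The mean shape is written as a PLY point cloud, the modes as a dense
#' CSV matrix, and eigenvalues plus metadata as JSON, all under one
#' directory.
#'
#' @param model a [ShapeModel-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeShapeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meanPts <- matrix(model@meanShape, ncol = 3L, byrow = TRUE)
  writePointCloud(pointCloud(meanPts, instanceId = "meanShape"),
    file.path(dir, "mean_shape.ply")
  )
  write.csv(model@modes, file.path(dir, "modes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      eigenvalues = model@eigenvalues, retained = model@retained,
      point_count = model@pointCount
    ),
    file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname writeShapeModel
#' @export
readShapeModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  meanPts <- readPointCloud(file.path(dir, "mean_shape.ply"))@points
  modes <- as.matrix(read.csv(file.path(dir, "modes.csv")))
  dimnames(modes) <- NULL
  new("ShapeModel",
    meanShape = as.vector(t(meanPts)), modes = modes,
    eigenvalues = as.numeric(meta$eigenvalues),
    retained = as.integer(meta$retained),
    pointCount = as.integer(meta$point_count)
  )
}
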