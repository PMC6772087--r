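#' Construct a SurfaceMesh
#'
#' Builds a validated [SurfaceMesh-class]. When `normals` is `NULL` they
#' are computed as the area-weighted average of incident face normals,
#' normalised to unit length — the usual convention for triangulated bone
#' surfaces exported from segmentation software.
#'
#' @param vertices numeric matrix, vertices x 3 (mm).
#' @param faces integer matrix, faces x 3, 1-based vertex indices with
#'   consistent outward (counter-clockwise) winding.
#' @param normals optional vertices x 3 matrix of unit normals.
#' @param instanceId instance label.
#' @return a [SurfaceMesh-class].
#' @examples
#' m <- tetrahedronMesh()
#' range(sqrt(rowSums(normals(m)^2)))  # all 1
#' @export
surfaceMesh <- function(vertices, faces, normals = NULL, instanceId = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopIf(nrow(vertices) >= 1L && (any(faces < 1L) || any(faces > nrow(vertices))),
    "face indices must refer to existing vertices"
  )
  if (is.null(normals)) normals <- vertexNormals(vertices, faces)
  new("SurfaceMesh",
    vertices = vertices, faces = faces,
    normals = as.matrix(normals), instanceId = as.character(instanceId)
  )
}

#' Construct a PointCloud
#'
#' @param points numeric matrix, points x 3.
#' @param normals optional points x 3 unit normals.
#' @param centroidSize centroid size recorded at normalisation (`NA`
#'   before [centerAndScale()] is applied).
#' @param instanceId instance label.
#' @return a [PointCloud-class].
#' @export
pointCloud <- function(points, normals = NULL, centroidSize = NA_real_,
                       instanceId = "cloud") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (is.null(normals)) {
    normals <- matrix(numeric(0), 0L, 3L)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
  }
  new("PointCloud",
    points = points, normals = normals,
    centroidSize = as.numeric(centroidSize), instanceId = as.character(instanceId)
  )
}

# Area-weighted vertex normals: each face's (unnormalised) cross product
# has magnitude 2 * area, so summing raw cross products over incident
# faces weights by area; the sum is then unit-normalised.
vertexNormals <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- crossProduct(e1, e2)
  acc <- matrix(0, nrow(vertices), 3L)
  for (k in 1:3) {
    s <- rowsum(cr, group = faces[, k])
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  len <- rowNorms(acc)
  if (any(len < 1e-12)) {
    stop("degenerate mesh: vertex with zero accumulated normal", call. = FALSE)
  }
  acc / len
}

faceAreas <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  0.5 * rowNorms(crossProduct(e1, e2))
}

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(object) object@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(object) object@faces)
#' @rdname accessors
#' @export
setMethod("normals", "SurfaceMesh", function(object) object@normals)
#' @rdname accessors
#' @export
setMethod("instanceId", "SurfaceMesh", function(object) object@instanceId)
#' @rdname accessors
#' @export
setMethod("points3d", "PointCloud", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("normals", "PointCloud", function(object) object@normals)
#' @rdname accessors
#' @export
setMethod("centroidSize", "PointCloud", function(object) object@centroidSize)
#' @rdname accessors
#' @export
setMethod("instanceId", "PointCloud", function(object) object@instanceId)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf(
    "SurfaceMesh '%s': %d vertices, %d faces\n",
    object@instanceId, nrow(object@vertices), nrow(object@faces)
  ))
})

setMethod("show", "PointCloud", function(object) {
  cs <- if (is.na(object@centroidSize)) "raw (mm)" else {
    sprintf("normalized (centroid size %.4g recorded)", object@centroidSize)
  }
  cat(sprintf(
    "PointCloud '%s': %d points, %s, normals: %s\n",
    object@instanceId, nrow(object@points), cs,
    if (nrow(object@normals) > 0L) "yes" else "no"
  ))
})

#' @rdname mirrorSagittal
#' @export
setMethod("mirrorSagittal", "SurfaceMesh", function(object, axis = 1L) {
  axis <- as.integer(axis)
  stopIf(axis < 1L || axis > 3L, "axis must be 1, 2 or 3")
  v <- object@vertices
  v[, axis] <- -v[, axis]
  n <- object@normals
  n[, axis] <- -n[, axis]
  # reversing the winding keeps normals outward after reflection
  f <- object@faces[, c(1L, 3L, 2L), drop = FALSE]
  new("SurfaceMesh",
    vertices = v, faces = f, normals = n,
    instanceId = object@instanceId
  )
})

#' @rdname mirrorSagittal
#' @export
setMethod("mirrorSagittal", "PointCloud", function(object, axis = 1L) {
  axis <- as.integer(axis)
  stopIf(axis < 1L || axis > 3L, "axis must be 1, 2 or 3")
  p <- object@points
  p[, axis] <- -p[, axis]
  n <- object@normals
  if (nrow(n) > 0L) n[, axis] <- -n[, axis]
  new("PointCloud",
    points = p, normals = n,
    centroidSize = object@centroidSize, instanceId = object@instanceId
  )
})

#' Centre a point cloud and scale it to unit centroid size
#'
#' Translates the points so their centroid is the origin and divides by
#' the centroid size — Kendall's definition, the square root of the summed
#' squared distances of the points from their centroid — the standard
#' morphometric size measure removed before shape analysis. The original
#' centroid size is recorded on the returned cloud.
#'
#' @param cloud a [PointCloud-class] with at least 2 distinct points.
#' @return a normalised [PointCloud-class] (centroid at origin, centroid
#'   size 1, original size in `centroidSize()`).
#' @examples
#' cl <- pointCloud(rbind(c(0, 0, 0), c(2, 0, 0)))
#' norm <- centerAndScale(cl)
#' centroidSize(norm)       # sqrt(2)
#' colSums(points3d(norm))  # origin centroid
#' @export
centerAndScale <- function(cloud) {
  stopIf(!is(cloud, "PointCloud"), "cloud must be a PointCloud")
  p <- cloud@points
  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  size <- sqrt(sum(pc^2))
  scaleRef <- max(abs(p)) + 1
  stopIf(size < 1e-12 * scaleRef,
    "zero centroid size: all points are identical"
  )
  new("PointCloud",
    points = pc / size, normals = cloud@normals,
    centroidSize = size, instanceId = cloud@instanceId
  )
}

#' Sample points area-uniformly on a mesh surface
#'
#' Stratified area-weighted sampling: each face receives
#' floor(n * area / totalArea) points and the remainder goes to the faces
#' with the largest fractional allocation; within a face points are drawn
#' uniformly in barycentric coordinates. Normals are barycentric
#' interpolations of the vertex normals. Deterministic given `seed`.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param n number of points (>= 4).
#' @param seed integer seed (mandatory for reproducibility).
#' @return a raw (mm-unit) [PointCloud-class] with interpolated unit
#'   normals.
#' @examples
#' cl <- sampleSurface(tetrahedronMesh(), 50, seed = 1)
#' nrow(points3d(cl))
#' @export
sampleSurface <- function(mesh, n, seed) {
  stopIf(!is(mesh, "SurfaceMesh"), "mesh must be a SurfaceMesh")
  n <- as.integer(n)
  stopIf(n < 4L, "n must be >= 4")
  stopIf(missing(seed) || is.null(seed), "seed is required")
  areas <- faceAreas(mesh@vertices, mesh@faces)
  frac <- n * areas / sum(areas)
  counts <- floor(frac)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(frac - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  faceIdx <- rep.int(seq_along(counts), counts)
  withSeed(seed, {
    u <- runif(n)
    v <- runif(n)
  })
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  w <- 1 - u - v
  f <- mesh@faces[faceIdx, , drop = FALSE]
  V <- mesh@vertices
  N <- mesh@normals
  pts <- w * V[f[, 1], , drop = FALSE] + u * V[f[, 2], , drop = FALSE] +
    v * V[f[, 3], , drop = FALSE]
  nrm <- w * N[f[, 1], , drop = FALSE] + u * N[f[, 2], , drop = FALSE] +
    v * N[f[, 3], , drop = FALSE]
  pointCloud(pts,
    normals = normalizeRows(nrm),
    instanceId = mesh@instanceId
  )
}

#' Smallest closed triangulated fixture: a regular tetrahedron
#'
#' @param scale edge-scaling factor.
#' @return a [SurfaceMesh-class] with 4 vertices and 4 faces.
#' @export
tetrahedronMesh <- function(scale = 1) {
  v <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  ) * scale
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  surfaceMesh(v, f, instanceId = "tetrahedron")
}

#' Icosphere mesh
#'
#' A unit sphere triangulated by recursive midpoint subdivision of an
#' icosahedron; subdivision levels 0..4 give 12, 42, 162, 642 and 2562
#' vertices. Used as the topology of the synthetic bone template.
#'
#' @param subdiv number of subdivision rounds (0-5).
#' @return a [SurfaceMesh-class] with unit-length vertices.
#' @export
icosphereMesh <- function(subdiv = 3L) {
  subdiv <- as.integer(subdiv)
  stopIf(subdiv < 0L || subdiv > 5L, "subdiv must be in 0..5")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    midIdx <- new.env(parent = emptyenv())
    verts <- v
    getMid <- function(a, b) {
      key <- edgeKey(a, b)
      idx <- midIdx[[key]]
      if (is.null(idx)) {
        mid <- (verts[a, ] + verts[b, ]) / 2
        mid <- mid / sqrt(sum(mid^2))
        verts <<- rbind(verts, mid)
        idx <- nrow(verts)
        midIdx[[key]] <- idx
      }
      idx
    }
    newF <- matrix(0L, 4L * nrow(f), 3L)
    r <- 1L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      newF[r, ] <- c(a, ab, ca)
      newF[r + 1L, ] <- c(b, bc, ab)
      newF[r + 2L, ] <- c(cc, ca, bc)
      newF[r + 3L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- verts
    f <- newF
  }
  surfaceMesh(v, f, instanceId = sprintf("icosphere%d", subdiv))
}
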