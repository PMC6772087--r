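#' Accessors for shape-analysis objects
#'
#' Standard accessors: `vertices()`, `faces()`, `normals()` for meshes;
#' `points3d()`, `normals()`, `centroidSize()`, `instanceId()` for point
#' clouds; `meanCloud()`, `transforms()` for aligned cohorts;
#' `meanShape()`, `modes()`, `eigenvalues()`, `retainedModes()` (with a
#' replacement form) and `pointCount()` for shape models.
#'
#' @param object an object of the matching class.
#' @param value replacement value (for `retainedModes<-`).
#' @return the slot contents (or the modified object for replacement
#'   forms).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("normals", function(object) standardGeneric("normals"))
#' @rdname accessors
#' @export
setGeneric("points3d", function(object) standardGeneric("points3d"))
#' @rdname accessors
#' @export
setGeneric("centroidSize", function(object) standardGeneric("centroidSize"))
#' @rdname accessors
#' @export
setGeneric("instanceId", function(object) standardGeneric("instanceId"))
#' @rdname accessors
#' @export
setGeneric("meanCloud", function(object) standardGeneric("meanCloud"))
#' @rdname accessors
#' @export
setGeneric("transforms", function(object) standardGeneric("transforms"))
#' @rdname accessors
#' @export
setGeneric("meanShape", function(object) standardGeneric("meanShape"))
#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("retainedModes", function(object) standardGeneric("retainedModes"))
#' @rdname accessors
#' @export
setGeneric("retainedModes<-", function(object, value) standardGeneric("retainedModes<-"))
#' @rdname accessors
#' @export
setGeneric("pointCount", function(object) standardGeneric("pointCount"))

#' Mirror a bone in the sagittal plane
#'
#' Negates the medial-lateral coordinate (declared axis, default the first
#' axis) so right-side bones can be analysed in a common left-side shape
#' space. For meshes the face winding is reversed so normals stay outward;
#' for point clouds the matching normal component is negated.
#'
#' @param object a [SurfaceMesh-class] or [PointCloud-class].
#' @param axis integer axis index of the medial-lateral direction
#'   (default 1); override for data with other coordinate conventions.
#' @return an object of the same class, mirrored.
#' @examples
#' m <- tetrahedronMesh()
#' m2 <- mirrorSagittal(mirrorSagittal(m))
#' stopifnot(identical(vertices(m), vertices(m2)))
#' @export
setGeneric("mirrorSagittal", function(object, axis = 1L) standardGeneric("mirrorSagittal"))
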