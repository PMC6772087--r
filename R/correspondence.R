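#' Establish a dense one-to-one correspondence across aligned instances
#'
#' Samples a template of `nPoints` points from the registered mean cloud
#' (a seeded subsample; when `nPoints` exceeds the mean-cloud size the
#' template is upsampled by midpoint interpolation between neighbouring
#' mean points) and matches it to every aligned instance by minimising,
#' per template point, the combined cost
#' `||delta position||^2 + normalWeight * ||delta normal||^2`, with a
#' strict one-to-one assignment enforced by solving the linear assignment
#' problem on the combined-cost matrix. Candidates are restricted to the
#' `kCandidates` positionally nearest instance points per template point
#' (non-candidates carry a prohibitive cost), which keeps the assignment
#' sparse in practice while the solver guarantees feasibility on the full
#' rectangular matrix. Rows are ordered identically across instances, so
#' the result feeds PCA directly.
#'
#' @param cohort a converged [AlignedCohort-class] (use `force = TRUE` to
#'   correspond an unconverged cohort).
#' @param nPoints number N of corresponded points; every instance must
#'   have at least N points.
#' @param normalWeight nonnegative weight of the normal term (on
#'   unit-size clouds with unit normals; default 0.1).
#' @param seed integer seed for the template draw.
#' @param kCandidates positional nearest-neighbour candidates per
#'   template point.
#' @param force allow unconverged cohorts.
#' @return a [CorrespondenceMatrix-class] of dimension instances x 3N.
#' @export
establishCorrespondence <- function(cohort, nPoints, normalWeight = 0.1,
                                    seed = 1L, kCandidates = 20L,
                                    force = FALSE) {
  stopIf(!is(cohort, "AlignedCohort"), "cohort must be an AlignedCohort")
  stopIf(!cohort@converged && !force,
    "cohort is not converged; pass force = TRUE to proceed anyway"
  )
  stopIf(normalWeight < 0, "normalWeight must be nonnegative")
  nPoints <- as.integer(nPoints)
  stopIf(nPoints < 1L, "nPoints must be positive")
  counts <- vapply(cohort@clouds, function(cl) nrow(cl@points), integer(1))
  stopIf(any(counts < nPoints), sprintf(
    "every instance needs at least nPoints = %d points (smallest has %d)",
    nPoints, min(counts)
  ))

  tmpl <- sampleTemplate(cohort@meanCloud, nPoints, seed)
  useNormals <- nrow(tmpl$normals) > 0L &&
    all(vapply(cohort@clouds, function(cl) nrow(cl@normals) > 0L, logical(1)))

  bigCost <- 1e8
  rows <- lapply(cohort@clouds, function(cl) {
    d2 <- pairwiseDist2(tmpl$points, cl@points)
    cost <- d2
    if (useNormals && normalWeight > 0) {
      cost <- cost + normalWeight * pairwiseDist2(tmpl$normals, cl@normals)
    }
    if (kCandidates < ncol(d2)) {
      keep <- matrix(FALSE, nrow(d2), ncol(d2))
      for (j in seq_len(nrow(d2))) {
        keep[j, order(d2[j, ])[seq_len(kCandidates)]] <- TRUE
      }
      cost[!keep] <- bigCost
    }
    idx <- .lapSolve(cost)
    stopIf(anyDuplicated(idx) > 0L, "internal error: assignment not one-to-one")
    as.vector(t(cl@points[idx, , drop = FALSE]))
  })
  ids <- vapply(cohort@clouds, function(cl) cl@instanceId, character(1))
  data <- do.call(rbind, rows)
  rownames(data) <- ids
  new("CorrespondenceMatrix",
    data = data, pointCount = nPoints,
    instanceIds = ids, templateId = "mean"
  )
}

# Template: seeded subsample of the mean cloud; midpoint upsampling with
# averaged normals when more points are requested than the mean has.
sampleTemplate <- function(meanCloud, nPoints, seed) {
  P <- meanCloud@points
  N <- meanCloud@normals
  hasN <- nrow(N) > 0L
  withSeed(seed, {
    if (nPoints <= nrow(P)) {
      idx <- sort(sample.int(nrow(P), nPoints))
      P <- P[idx, , drop = FALSE]
      if (hasN) N <- N[idx, , drop = FALSE]
    } else {
      need <- nPoints - nrow(P)
      d2 <- pairwiseDist2(P, P)
      diag(d2) <- Inf
      nn <- apply(d2, 1L, which.min)
      pick <- sample.int(nrow(P), need, replace = need > nrow(P))
      midP <- (P[pick, , drop = FALSE] + P[nn[pick], , drop = FALSE]) / 2
      P <- rbind(P, midP)
      if (hasN) {
        midN <- normalizeRows(N[pick, , drop = FALSE] + N[nn[pick], , drop = FALSE])
        N <- rbind(N, midN)
      }
    }
  })
  list(points = P, normals = if (hasN) N else matrix(numeric(0), 0L, 3L))
}

#' Correspondence quality summary
#'
#' Per template point, the mean across instance pairs of corresponded
#' point distances, plus cohort-level mean and maximum. Identical
#' instances give zeros; large per-point values localise badly matched
#' surface regions.
#'
#' @param x a [CorrespondenceMatrix-class] with >= 2 instances.
#' @return a list with `perPoint` (length-N vector), `mean` and `max`.
#' @export
correspondenceQuality <- function(x) {
  stopIf(!is(x, "CorrespondenceMatrix"), "input must be a CorrespondenceMatrix")
  X <- x@data
  nInst <- nrow(X)
  stopIf(nInst < 2L, "need at least 2 instances")
  N <- x@pointCount
  acc <- numeric(N)
  nPairs <- 0L
  for (a in seq_len(nInst - 1L)) {
    for (b in (a + 1L):nInst) {
      diff <- X[a, ] - X[b, ]
      d <- sqrt(colSums(matrix(diff^2, nrow = 3L)))
      acc <- acc + d
      nPairs <- nPairs + 1L
    }
  }
  perPoint <- acc / nPairs
  list(perPoint = perPoint, mean = mean(perPoint), max = max(perPoint))
}

#' @rdname accessors
#' @export
setMethod("pointCount", "CorrespondenceMatrix", function(object) object@pointCount)

setMethod("show", "CorrespondenceMatrix", function(object) {
  cat(sprintf(
    "CorrespondenceMatrix: %d instances x %d points (%d columns)\n",
    nrow(object@data), object@pointCount, ncol(object@data)
  ))
})

#' Write / read a correspondence matrix as CSV with a JSON sidecar
#'
#' @param x a [CorrespondenceMatrix-class].
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeCorrespondence <- function(x, path) {
  write.csv(x@data, path, row.names = TRUE)
  jsonlite::write_json(
    list(
      point_count = x@pointCount,
      instance_ids = x@instanceIds,
      template_id = x@templateId
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeCorrespondence
#' @export
readCorrespondence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  new("CorrespondenceMatrix",
    data = as.matrix(df), pointCount = as.integer(meta$point_count),
    instanceIds = as.character(meta$instance_ids),
    templateId = as.character(meta$template_id)
  )
}
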