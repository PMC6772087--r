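#' Construct a SimilarityTransform
#'
#' @param rotation 3 x 3 proper rotation matrix (default identity).
#' @param translation length-3 vector (default zero).
#' @param scale positive scalar (default 1).
#' @return a [SimilarityTransform-class].
#' @export
similarityTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                scale = 1) {
  new("SimilarityTransform",
    rotation = rotation, translation = as.numeric(translation),
    scale = as.numeric(scale)
  )
}

setMethod("show", "SimilarityTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf(
    "SimilarityTransform: rotation %.2f deg, scale %.4g, |t| = %.4g\n",
    ang, object@scale, sqrt(sum(object@translation^2))
  ))
})

#' Registration parameter set
#'
#' Defaults follow common practice for tarsal bones: sigma = 3 mm,
#' nMean = 2000 mean-cloud points, lambda = 1e-6, tol = 1e-6 and at most
#' 200 outer iterations. For the talus lambda = 1e-6 and for the
#' calcaneus lambda = 5e-4 are the published settings.
#'
#' @param sigma Gaussian kernel width (mm, pre-normalisation units).
#' @param nMean points in the evolving mean cloud.
#' @param lambda mean-update stiffness (dimensionless, >= 0).
#' @param maxIters maximum outer iterations.
#' @param tol relative Frobenius convergence tolerance on the mean.
#' @param tolAligned pose-stability tolerance: RMS per-point motion of
#'   the aligned clouds between consecutive outer iterations.
#' @param wOutlier uniform-outlier component weight.
#' @param innerIters maximum inner EM iterations per instance.
#' @param innerTol inner EM relative log-likelihood tolerance.
#' @param annealSigma re-estimate the kernel width by EM (default TRUE).
#' @param sigmaFloorFactor floor of the annealed width as a fraction of
#'   the mean cloud's median nearest-neighbour spacing (default 0.5).
#' @return a [RegistrationParams-class].
#' @export
registrationParams <- function(sigma = 3, nMean = 2000L, lambda = 1e-6,
                               maxIters = 200L, tol = 1e-6,
                               tolAligned = 1e-5, wOutlier = 0.01,
                               innerIters = 8L, innerTol = 1e-8,
                               annealSigma = TRUE, sigmaFloorFactor = 0.5) {
  new("RegistrationParams",
    sigma = as.numeric(sigma), nMean = as.integer(nMean),
    lambda = as.numeric(lambda), maxIters = as.integer(maxIters),
    tol = as.numeric(tol), tolAligned = as.numeric(tolAligned),
    wOutlier = as.numeric(wOutlier),
    innerIters = as.integer(innerIters), innerTol = as.numeric(innerTol),
    annealSigma = isTRUE(annealSigma),
    sigmaFloorFactor = as.numeric(sigmaFloorFactor)
  )
}

#' Apply a similarity transform to a point cloud
#'
#' Points are mapped by `scale * R p + t`; normals are rotated only and
#' re-normalised. Reflections are rejected by the transform's validity
#' (mirroring must go through [mirrorSagittal()]).
#'
#' @param cloud a [PointCloud-class].
#' @param transform a [SimilarityTransform-class].
#' @return the transformed [PointCloud-class].
#' @export
applyTransform <- function(cloud, transform) {
  stopIf(!is(cloud, "PointCloud"), "cloud must be a PointCloud")
  stopIf(!is(transform, "SimilarityTransform"), "transform must be a SimilarityTransform")
  validObject(transform)
  p <- transform@scale * cloud@points %*% t(transform@rotation)
  p <- sweep(p, 2L, transform@translation, "+")
  n <- cloud@normals
  if (nrow(n) > 0L) n <- normalizeRows(n %*% t(transform@rotation))
  new("PointCloud",
    points = p, normals = n,
    centroidSize = cloud@centroidSize, instanceId = cloud@instanceId
  )
}

#' Compose and invert similarity transforms
#'
#' `composeTransforms(a, b)` is the transform applying `b` first, then
#' `a`; `invertTransform(t)` satisfies
#' `composeTransforms(t, invertTransform(t)) == identity`.
#'
#' @param a,b,transform [SimilarityTransform-class] objects.
#' @return a [SimilarityTransform-class].
#' @export
composeTransforms <- function(a, b) {
  similarityTransform(
    rotation = a@rotation %*% b@rotation,
    translation = a@scale * as.vector(a@rotation %*% b@translation) + a@translation,
    scale = a@scale * b@scale
  )
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  similarityTransform(
    rotation = Rt,
    translation = -as.vector(Rt %*% transform@translation) / transform@scale,
    scale = 1 / transform@scale
  )
}

# Principal-axes initialisation: rotate the instance's covariance
# eigenvectors onto the mean's, trying the four proper sign combinations
# and keeping the one with the smallest mean nearest-neighbour distance.
# Blob-like bones have well-separated principal axes, so this lands the
# EM close to its basin.
pcaInitTransform <- function(Y, M, nProbe = 80L) {
  ey <- eigen(stats::cov(Y), symmetric = TRUE)$vectors
  em <- eigen(stats::cov(M), symmetric = TRUE)$vectors
  need <- det(em) * det(ey)
  s0 <- sqrt(mean(rowSums(M^2)) / mean(rowSums(Y^2)))
  probe <- Y[round(seq(1L, nrow(Y), length.out = min(nProbe, nrow(Y)))), , drop = FALSE]
  best <- NULL
  bestScore <- Inf
  for (s1 in c(1, -1)) {
    for (s2 in c(1, -1)) {
      s3 <- need * s1 * s2
      R <- em %*% diag(c(s1, s2, s3)) %*% t(ey)
      d2 <- pairwiseDist2(s0 * probe %*% t(R), M)
      score <- mean(apply(d2, 1L, min))
      if (score < bestScore) {
        bestScore <- score
        best <- R
      }
    }
  }
  similarityTransform(best, c(0, 0, 0), s0)
}

# Inner EM: similarity alignment of one instance Y (n x 3) to the GMM
# whose centroids are the current mean cloud M (m x 3), kernel width
# sigma. Coherent-point-drift-style responsibilities with a uniform
# outlier component; closed-form weighted Umeyama similarity M-step;
# optional closed-form sigma^2 re-estimation (annealing). Returns the
# transform, the responsibility matrix, the final sigma^2 and the
# (monotone) log-likelihood trace.
cpdSimilarity <- function(Y, M, sigma2Init, params, init = NULL,
                          initTransform = NULL, sigma2Floor = 1e-12,
                          sRef = NULL) {
  n <- nrow(Y)
  m <- nrow(M)
  w <- params@wOutlier
  # size is already removed by centroid-size normalisation, so the
  # aligned scale must stay near the RMS-radius ratio; bounding it
  # prevents the scale-collapse pathology of wide-kernel EM starts
  if (is.null(sRef)) sRef <- sqrt(mean(rowSums(M^2)) / mean(rowSums(Y^2)))
  rM2 <- mean(rowSums(M^2))
  vol <- prod(pmax(apply(M, 2L, function(x) diff(range(x))), 1e-6))
  coldStart <- is.null(init)
  tr <- if (!is.null(init)) init else {
    if (is.null(initTransform)) similarityTransform() else initTransform
  }
  s <- tr@scale; R <- tr@rotation; tvec <- tr@translation
  TY <- sweep(s * Y %*% t(R), 2L, tvec, "+")
  sigma2 <- sigma2Init
  if (params@annealSigma && coldStart) {
    # cold start: widen the kernel to the data spread (the classic
    # coherent-point-drift initialisation) so EM sees global structure
    # and can escape the initial misalignment, then anneal
    sigma2 <- max(sigma2, sum(pairwiseDist2(TY, M)) / (3 * n * m))
  }
  ll <- -Inf
  llTrace <- numeric(0)
  P <- NULL
  M2sum <- rowSums(M^2)
  for (it in seq_len(params@innerIters)) {
    es <- .cpdEStep(TY, Y, M, sigma2, w, vol)
    P <- es$P
    llNew <- es$logLik
    llTrace <- c(llTrace, llNew)
    W <- es$W
    if (W < 1e-12) break
    ybar <- es$Sy / W
    xbar <- es$S2 / W
    # weighted cross-covariance; the xbar term vanishes against ybar
    A <- es$S1 - tcrossprod(es$S2, ybar)
    sv <- svd(A)
    d <- sign(det(sv$u %*% t(sv$v)))
    S <- diag(c(1, 1, d))
    R <- sv$u %*% S %*% t(sv$v)
    denomS <- es$sumPkY2 - W * sum(ybar^2)
    s <- sum(diag(S) * sv$d) / denomS
    if (!is.finite(s) || s <= 0) s <- sRef
    if (params@annealSigma && sigma2 > 0.09 * rM2) {
      # wide-kernel phase: the scale estimate degenerates towards the
      # blurred centroid; hold it at the RMS-radius reference (size was
      # already removed by normalisation) until the kernel has annealed
      s <- sRef
    }
    s <- min(max(s, 0.7 * sRef), 1.4 * sRef)
    tvec <- xbar - s * as.vector(R %*% ybar)
    TY <- sweep(s * Y %*% t(R), 2L, tvec, "+")
    if (params@annealSigma) {
      E <- sum(es$pk * rowSums(TY^2)) - 2 * sum(TY * es$PM) + sum(es$cs * M2sum)
      sigma2 <- max(E / (3 * W), sigma2Floor)
    }
    if (is.finite(ll) && abs(llNew - ll) < params@innerTol * abs(llNew)) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  list(
    transform = similarityTransform(R, tvec, s),
    P = P, sigma2 = sigma2, logLik = ll, llTrace = llTrace
  )
}

#' Groupwise similarity registration to an evolving Gaussian-mixture mean
#'
#' Aligns all instances of one bone type to an evolving mean point cloud
#' so that no single specimen biases the atlas. Each cloud must already be
#' centred and scaled to unit centroid size ([centerAndScale()]). The mean
#' is initialised as a seeded subsample of the first instance; each outer
#' iteration (a) re-estimates, per instance, the similarity transform
#' maximising a Gaussian-mixture alignment likelihood against the current
#' mean (EM with closed-form similarity updates, kernel width `sigma`
#' interpreted in mm and divided by the instance's recorded centroid
#' size), (b) re-estimates every mean point as the responsibility-weighted
#' average of matched instance points with a `lambda`-weighted proximal
#' pull towards its previous position, and (c) re-centres and re-scales
#' the mean to unit centroid size, which removes global drift
#' (unbiasedness). Iteration stops when the relative Frobenius change of
#' the mean falls below `tol`.
#'
#' @param clouds list of normalised [PointCloud-class] objects (>= 2).
#' @param params a [RegistrationParams-class].
#' @param seed integer seed controlling the mean initialisation.
#' @param meanInit "subsample" (default) or "kmeans" initialisation of the
#'   mean cloud from the first instance.
#' @param initMethod per-instance initial alignment: "identity" (default;
#'   appropriate when instances arrive in roughly common orientation, as
#'   with anatomically oriented scans) or "principal-axes" (aligns
#'   covariance eigenvectors first; helps with large unknown rotations
#'   but can flip near-symmetric shapes).
#' @return an [AlignedCohort-class]. On non-convergence the cohort is
#'   returned with `converged = FALSE` and a warning, not an error.
#' @export
groupwiseRegister <- function(clouds, params = registrationParams(), seed = 1L,
                              meanInit = c("subsample", "kmeans"),
                              initMethod = c("identity", "principal-axes")) {
  meanInit <- match.arg(meanInit)
  initMethod <- match.arg(initMethod)
  stopIf(length(clouds) < 2L, "need at least 2 clouds")
  for (cl in clouds) {
    stopIf(!is(cl, "PointCloud"), "clouds must be PointCloud objects")
    ctr <- colMeans(cl@points)
    size <- sqrt(sum(sweep(cl@points, 2L, ctr)^2))
    stopIf(max(abs(ctr)) > 1e-6 || abs(size - 1) > 1e-6,
      sprintf(
        "cloud '%s' is not normalized (run centerAndScale first)",
        cl@instanceId
      )
    )
  }
  nInst <- length(clouds)
  P1 <- clouds[[1]]@points
  nMean <- min(params@nMean, nrow(P1))
  M <- withSeed(seed, {
    if (meanInit == "kmeans") {
      stats::kmeans(P1, centers = nMean, iter.max = 30L, nstart = 1L)$centers
    } else {
      P1[sort(sample.int(nrow(P1), nMean)), , drop = FALSE]
    }
  })
  # sigma in mm -> unit-size scale via each instance's recorded size
  sigma2Init <- vapply(clouds, function(cl) {
    cs <- cl@centroidSize
    if (is.na(cs)) cs <- 1
    (params@sigma / cs)^2
  }, numeric(1))
  transformsList <- lapply(clouds, function(cl) {
    if (initMethod == "principal-axes") {
      pcaInitTransform(cl@points, M)
    } else {
      # identity orientation; the scale absorbs the RMS-radius mismatch
      # between instance and mean point counts
      similarityTransform(
        scale = sqrt(mean(rowSums(M^2)) / mean(rowSums(cl@points^2)))
      )
    }
  })
  coldStart <- rep(TRUE, nInst)
  sigma2State <- as.list(sigma2Init)
  d2m <- pairwiseDist2(M, M)
  diag(d2m) <- Inf
  spacing <- stats::median(sqrt(apply(d2m, 1L, min)))
  sigma2Floor <- max((params@sigmaFloorFactor * spacing)^2, 1e-12)
  logRows <- vector("list", params@maxIters)
  converged <- FALSE
  itRun <- 0L
  lamEff <- params@lambda * nInst
  prevAligned <- NULL
  for (it in seq_len(params@maxIters)) {
    itRun <- it
    num <- matrix(0, nrow(M), 3L)
    den <- numeric(nrow(M))
    llTot <- 0
    alignedPts <- vector("list", nInst)
    for (i in seq_len(nInst)) {
      fit <- cpdSimilarity(
        clouds[[i]]@points, M, sigma2State[[i]], params,
        init = if (coldStart[i]) NULL else transformsList[[i]],
        initTransform = transformsList[[i]], sigma2Floor = sigma2Floor
      )
      coldStart[i] <- FALSE
      transformsList[[i]] <- fit$transform
      sigma2State[[i]] <- fit$sigma2
      llTot <- llTot + fit$logLik
      TY <- applyTransform(clouds[[i]], fit$transform)@points
      alignedPts[[i]] <- TY
      num <- num + crossprod(fit$P, TY)
      den <- den + colSums(fit$P)
    }
    alignedChange <- if (is.null(prevAligned)) Inf else {
      max(vapply(seq_len(nInst), function(i) {
        sqrt(mean(rowSums((alignedPts[[i]] - prevAligned[[i]])^2)))
      }, numeric(1)))
    }
    prevAligned <- alignedPts
    Mnew <- (num + lamEff * M) / (den + lamEff)
    zero <- den + lamEff < 1e-12
    if (any(zero)) Mnew[zero, ] <- M[zero, , drop = FALSE]
    # re-centre and re-scale the mean: the unbiasedness constraint
    ctr <- colMeans(Mnew)
    Mnew <- sweep(Mnew, 2L, ctr)
    Mnew <- Mnew / sqrt(sum(Mnew^2))
    change <- sqrt(sum((Mnew - M)^2)) / sqrt(sum(M^2))
    logRows[[it]] <- data.frame(
      iteration = it, meanChange = change,
      alignedChange = alignedChange, logLik = llTot
    )
    M <- Mnew
    if (change < params@tol || alignedChange < params@tolAligned) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "groupwise registration did not converge within %d iterations (last change %.3g)",
      params@maxIters, logRows[[itRun]]$meanChange
    ), call. = FALSE)
  }
  aligned <- lapply(seq_len(nInst), function(i) {
    applyTransform(clouds[[i]], transformsList[[i]])
  })
  meanNormals <- meanCloudNormals(M, aligned)
  meanPC <- new("PointCloud",
    points = M, normals = meanNormals,
    centroidSize = 1, instanceId = "mean"
  )
  new("AlignedCohort",
    clouds = aligned, meanCloud = meanPC, transforms = transformsList,
    iterationsRun = itRun, converged = converged,
    log = do.call(rbind, logRows[seq_len(itRun)]), params = params
  )
}

# Mean-cloud normals: average of the normals of the k nearest pooled
# aligned points, unit-normalised. Sign-coherent because all instances
# are aligned.
meanCloudNormals <- function(M, aligned, k = 8L) {
  hasN <- all(vapply(aligned, function(cl) nrow(cl@normals) > 0L, logical(1)))
  if (!hasN) return(matrix(numeric(0), 0L, 3L))
  pooledP <- do.call(rbind, lapply(aligned, function(cl) cl@points))
  pooledN <- do.call(rbind, lapply(aligned, function(cl) cl@normals))
  d2 <- pairwiseDist2(M, pooledP)
  k <- min(k, ncol(d2))
  out <- matrix(0, nrow(M), 3L)
  for (j in seq_len(nrow(M))) {
    thr <- sort.int(d2[j, ], partial = k)[k]
    nn <- which(d2[j, ] <= thr)[seq_len(k)]
    out[j, ] <- colSums(pooledN[nn, , drop = FALSE])
  }
  bad <- rowNorms(out) < 1e-9
  if (any(bad)) out[bad, 1] <- 1
  normalizeRows(out)
}

#' @rdname accessors
#' @export
setMethod("meanCloud", "AlignedCohort", function(object) object@meanCloud)
#' @rdname accessors
#' @export
setMethod("transforms", "AlignedCohort", function(object) object@transforms)

setMethod("show", "AlignedCohort", function(object) {
  cat(sprintf(
    "AlignedCohort: %d instances, mean cloud of %d points, %d iterations, %s\n",
    length(object@clouds), nrow(object@meanCloud@points),
    object@iterationsRun,
    if (object@converged) "converged" else "NOT converged"
  ))
})

#' Serialise per-instance transforms to JSON
#'
#' Writes each transform as a 4 x 4 homogeneous matrix (rotation and
#' translation; the isotropic scale folded in) plus the scalar scale.
#'
#' @param cohort an [AlignedCohort-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTransforms <- function(cohort, path) {
  entries <- lapply(seq_along(cohort@transforms), function(i) {
    tr <- cohort@transforms[[i]]
    H <- diag(4)
    H[1:3, 1:3] <- tr@scale * tr@rotation
    H[1:3, 4] <- tr@translation
    list(
      instance_id = cohort@clouds[[i]]@instanceId,
      matrix = H, scale = tr@scale
    )
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
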