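#' Configure the synthetic bone-cohort generator
#'
#' Defaults emulate a two-arm tarsal-bone study: 26 unilateral CAI
#' subjects each contributing an ipsilateral (CAI) and a contralateral
#' (CAI_CONTRA) instance, and 26 healthy controls of whom 20 contribute
#' both ankles and 6 one ankle — 98 instances in total. Shape variation
#' is carried by orthonormal smooth latent deformation fields with a
#' strictly decreasing variance spectrum; a group mean offset is planted
#' on one designated mode, identical (by default) in ipsilateral and
#' contralateral instances. Instances receive per-vertex measurement
#' noise along vertex normals, a random similarity transform, and
#' right-side instances are mirrored.
#'
#' @param nCai unilateral CAI subjects.
#' @param nHealthy healthy subjects.
#' @param nBilateralHealthy healthy subjects with both sides scanned.
#' @param templateSubdiv icosphere subdivision of the template
#'   (default 4: 2562 vertices).
#' @param semiAxes superellipsoid semi-axes in mm (default 30, 22, 18 — a
#'   compact tarsal-bone-sized blob).
#' @param exponent superellipsoid exponent (default 2.5, slightly boxier
#'   than an ellipsoid).
#' @param nBumps,bumpAmp,bumpWidth smooth radial bumps (relative
#'   amplitude and angular width) giving the blob bone-like features.
#' @param latentModes number k of latent deformation modes (default 4).
#' @param spectrum latent variances in mm^2, strictly decreasing
#'   (default 400, 200, 100, 50 — a few millimetres of shape SD
#'   distributed over the surface).
#' @param effectMode mode carrying the group difference (default 2).
#' @param effectSize group mean offset in SD units (default 0, the null).
#' @param contraFraction fraction of the effect in contralateral
#'   instances (default 1: bone shape does not vary within a subject).
#' @param noiseSd per-vertex noise SD in mm (default 0.1).
#' @param rotMaxDeg,transMax,scaleRange similarity-transform ranges
#'   (defaults: rotations up to 30 degrees, translations up to 20 mm,
#'   scale 0.8-1.2).
#' @param ageRangeCai,ageRangeHealthy uniform age ranges (defaults
#'   18-50 and 20-55 years, echoing patient groups younger than
#'   controls).
#' @param genderRatio probability of male (default 0.5).
#' @param confoundAgeSlope optional age coupling into the effect mode
#'   (latent SD units per year, default 0).
#' @param seed root seed.
#' @return a validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(nCai = 26L, nHealthy = 26L,
                            nBilateralHealthy = 20L, templateSubdiv = 4L,
                            semiAxes = c(30, 22, 18), exponent = 2.5,
                            nBumps = 6L, bumpAmp = 0.08, bumpWidth = 0.15,
                            latentModes = 4L,
                            spectrum = c(400, 200, 100, 50),
                            effectMode = 2L, effectSize = 0,
                            contraFraction = 1, noiseSd = 0.1,
                            rotMaxDeg = 30, transMax = 20,
                            scaleRange = c(0.8, 1.2),
                            ageRangeCai = c(18, 50),
                            ageRangeHealthy = c(20, 55),
                            genderRatio = 0.5, confoundAgeSlope = 0,
                            seed = 1L) {
  new("GeneratorConfig",
    nCai = as.integer(nCai), nHealthy = as.integer(nHealthy),
    nBilateralHealthy = as.integer(nBilateralHealthy),
    templateSubdiv = as.integer(templateSubdiv),
    semiAxes = as.numeric(semiAxes), exponent = as.numeric(exponent),
    nBumps = as.integer(nBumps), bumpAmp = as.numeric(bumpAmp),
    bumpWidth = as.numeric(bumpWidth), latentModes = as.integer(latentModes),
    spectrum = as.numeric(spectrum), effectMode = as.integer(effectMode),
    effectSize = as.numeric(effectSize),
    contraFraction = as.numeric(contraFraction), noiseSd = as.numeric(noiseSd),
    rotMaxDeg = as.numeric(rotMaxDeg), transMax = as.numeric(transMax),
    scaleRange = as.numeric(scaleRange),
    ageRangeCai = as.numeric(ageRangeCai),
    ageRangeHealthy = as.numeric(ageRangeHealthy),
    genderRatio = as.numeric(genderRatio),
    confoundAgeSlope = as.numeric(confoundAgeSlope), seed = as.integer(seed)
  )
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    paste0(
      "GeneratorConfig: %d CAI + %d healthy subjects (%d bilateral), ",
      "%d latent modes, effect %.2f SD on mode %d, seed %d\n"
    ),
    object@nCai, object@nHealthy, object@nBilateralHealthy,
    object@latentModes, object@effectSize, object@effectMode, object@seed
  ))
})

# superellipsoid radius along unit direction u: t with
# sum_i |t u_i / a_i|^p = 1
superellipsoidRadius <- function(u, semiAxes, p) {
  s <- rowSums(abs(sweep(u, 2L, semiAxes, "/"))^p)
  s^(-1 / p)
}

#' Build the synthetic template bone
#'
#' A closed, watertight mesh: an icosphere warped onto a superellipsoid
#' with smooth seeded radial bumps, approximating a compact
#' tarsal-bone-like blob. Deterministic given the config seed.
#'
#' @param config a [GeneratorConfig-class].
#' @return a [SurfaceMesh-class].
#' @export
makeTemplate <- function(config = generatorConfig()) {
  sph <- icosphereMesh(config@templateSubdiv)
  u <- sph@vertices
  r <- superellipsoidRadius(u, config@semiAxes, config@exponent)
  if (config@nBumps > 0L && config@bumpAmp > 0) {
    bumps <- withSeed(deriveSeed(config@seed, 101L), {
      d <- matrix(rnorm(3L * config@nBumps), ncol = 3L)
      d <- normalizeRows(d)
      amp <- runif(config@nBumps, -config@bumpAmp, config@bumpAmp)
      list(d = d, amp = amp)
    })
    # geodesic-like bump profile from the dot product with bump centres
    for (g in seq_len(config@nBumps)) {
      ang <- 1 - u %*% bumps$d[g, ]
      r <- r * (1 + bumps$amp[g] * exp(-ang / config@bumpWidth))
    }
  }
  surfaceMesh(u * as.vector(r), sph@faces, instanceId = "template")
}

# low-order real spherical harmonics (l = 1, 2) on unit directions
harmonicBasis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x, y, z, x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1)
}

#' Orthonormal smooth latent deformation fields
#'
#' Builds k displacement fields over the template vertices from low-order
#' spherical-harmonic scalar profiles combined with radial and axis
#' displacement directions, mixed by a seeded random rotation and
#' orthonormalised (QR) over the 3V-dimensional vertex space. The fields
#' are smooth by construction and mutually orthonormal to machine
#' precision.
#'
#' @param template the template [SurfaceMesh-class].
#' @param k number of fields (at most 32 with the built-in basis).
#' @param seed integer seed.
#' @return a 3V x k matrix with orthonormal columns; each column reshapes
#'   to a V x 3 displacement field (x, y, z interleaved per vertex).
#' @export
makeLatentModes <- function(template, k, seed = 1L) {
  k <- as.integer(k)
  stopIf(k < 1L, "k must be >= 1")
  V <- template@vertices
  u <- normalizeRows(V)
  H <- harmonicBasis(u)
  nb <- ncol(H)
  dirs <- list(
    u,
    cbind(1, 0, 0)[rep(1L, nrow(V)), , drop = FALSE],
    cbind(0, 1, 0)[rep(1L, nrow(V)), , drop = FALSE],
    cbind(0, 0, 1)[rep(1L, nrow(V)), , drop = FALSE]
  )
  cand <- matrix(0, 3L * nrow(V), nb * length(dirs))
  cIdx <- 0L
  for (d in dirs) {
    for (j in seq_len(nb)) {
      cIdx <- cIdx + 1L
      field <- H[, j] * d
      cand[, cIdx] <- as.vector(t(field))
    }
  }
  stopIf(k > ncol(cand), sprintf(
    "k = %d exceeds the available smooth basis size %d", k, ncol(cand)
  ))
  mix <- withSeed(seed, matrix(rnorm(ncol(cand) * k), ncol(cand), k))
  Q <- qr.Q(qr(cand %*% mix))[, seq_len(k), drop = FALSE]
  # pin signs for reproducibility
  for (j in seq_len(k)) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

randomRotation <- function(maxDeg) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, maxDeg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L, 3L)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Generate a virtual bone cohort with known ground truth
#'
#' Draws per-instance latent coordinates from the configured spectrum,
#' plants the group mean offset on the effect mode (full strength in CAI
#' instances, `contraFraction` of it in contralateral instances), builds
#' each instance as template + deformation + normal-direction noise,
#' applies a random similarity transform, and mirrors right-side
#' instances. Byte-identical outputs for identical config and seed.
#'
#' @param config a [GeneratorConfig-class].
#' @return list with `meshes` (list of [SurfaceMesh-class]), `metadata`
#'   (data.frame: subject_id, instance_id, group, side, age, gender) and
#'   `groundTruth` (per-instance true transform, latent coordinates,
#'   mirroring, plus the latent mode matrix and template).
#' @export
sampleCohort <- function(config = generatorConfig()) {
  template <- makeTemplate(config)
  fields <- makeLatentModes(template, config@latentModes,
    seed = deriveSeed(config@seed, 202L)
  )
  V <- template@vertices
  Nrm <- template@normals
  k <- config@latentModes

  subjects <- list()
  sIdx <- 0L
  withSeed(deriveSeed(config@seed, 303L), {
    for (i in seq_len(config@nCai)) {
      sIdx <- sIdx + 1L
      affected <- if (runif(1) < 0.62) "R" else "L"
      subjects[[sIdx]] <- list(
        id = sprintf("CAI%02d", i), kind = "cai", affected = affected,
        age = runif(1, config@ageRangeCai[1], config@ageRangeCai[2]),
        gender = if (runif(1) < config@genderRatio) "M" else "F"
      )
    }
    for (i in seq_len(config@nHealthy)) {
      sIdx <- sIdx + 1L
      subjects[[sIdx]] <- list(
        id = sprintf("HC%02d", i), kind = "healthy",
        bilateral = i <= config@nBilateralHealthy,
        age = runif(1, config@ageRangeHealthy[1], config@ageRangeHealthy[2]),
        gender = if (runif(1) < config@genderRatio) "M" else "F"
      )
    }

    meshes <- list()
    meta <- list()
    gt <- list()
    n <- 0L
    emit <- function(subj, group, side) {
      n <<- n + 1L
      z <- rnorm(k) * sqrt(config@spectrum)
      if (group %in% c("CAI", "CAI_CONTRA")) {
        fr <- if (group == "CAI") 1 else config@contraFraction
        z[config@effectMode] <- z[config@effectMode] +
          fr * config@effectSize * sqrt(config@spectrum[config@effectMode])
      }
      if (config@confoundAgeSlope != 0) {
        z[config@effectMode] <- z[config@effectMode] +
          config@confoundAgeSlope * subj$age * sqrt(config@spectrum[config@effectMode])
      }
      disp <- matrix(fields %*% z, ncol = 3L, byrow = TRUE)
      verts <- V + disp
      if (config@noiseSd > 0) {
        verts <- verts + Nrm * rnorm(nrow(V), sd = config@noiseSd)
      }
      id <- sprintf("%s_%s", subj$id, side)
      mesh <- surfaceMesh(verts, template@faces, instanceId = id)
      mirrored <- side == "R"
      if (mirrored) mesh <- mirrorSagittal(mesh)
      R <- randomRotation(config@rotMaxDeg)
      tvec <- runif(3, -config@transMax, config@transMax)
      s <- runif(1, config@scaleRange[1], config@scaleRange[2])
      mv <- sweep(s * mesh@vertices %*% t(R), 2L, tvec, "+")
      meshes[[n]] <<- surfaceMesh(mv, mesh@faces, instanceId = id)
      meta[[n]] <<- data.frame(
        subject_id = subj$id, instance_id = id, group = group, side = side,
        age = subj$age, gender = subj$gender
      )
      gt[[n]] <<- list(
        instance_id = id, latent = z, mirrored = mirrored,
        transform = similarityTransform(R, tvec, s)
      )
    }
    for (subj in subjects) {
      if (subj$kind == "cai") {
        other <- if (subj$affected == "R") "L" else "R"
        emit(subj, "CAI", subj$affected)
        emit(subj, "CAI_CONTRA", other)
      } else {
        emit(subj, "HEALTHY", "L")
        if (subj$bilateral) emit(subj, "HEALTHY", "R")
      }
    }
    list(
      meshes = meshes,
      metadata = do.call(rbind, meta),
      groundTruth = list(
        instances = gt, fields = fields, template = template,
        config = config
      )
    )
  })
}

#' Write a sampled cohort to disk
#'
#' Per-instance PLY meshes, the metadata CSV (schema of
#' [makeCohortTable()]) and a ground-truth JSON.
#'
#' @param cohort output of [sampleCohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort$meshes) {
    writeMesh(m, file.path(dir, paste0(m@instanceId, ".ply")))
  }
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  gt <- lapply(cohort$groundTruth$instances, function(g) {
    list(
      instance_id = g$instance_id, latent = g$latent, mirrored = g$mirrored,
      rotation = g$transform@rotation, translation = g$transform@translation,
      scale = g$transform@scale
    )
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
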