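#' Read a triangulated surface mesh
#'
#' Reads PLY (ASCII and binary little-endian), STL (ASCII and binary) or
#' OBJ files into a [SurfaceMesh-class]. Per-vertex normals are always
#' recomputed from the triangulation (area-weighted incident-face
#' average), so meshes from different exporters carry consistent normals.
#' STL soups are welded on exact duplicate coordinates.
#'
#' @param path file path.
#' @param format one of "auto" (by extension), "ply", "stl", "obj".
#' @param instanceId label for the instance; defaults to the file name
#'   without extension.
#' @return a [SurfaceMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "ply", "stl", "obj"),
                     instanceId = NULL) {
  format <- match.arg(format)
  stopIf(!file.exists(path), sprintf("cannot read mesh: no such file '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    stopIf(!ext %in% c("ply", "stl", "obj"),
      sprintf("cannot infer mesh format from extension of '%s'", path)
    )
    format <- ext
  }
  if (is.null(instanceId)) {
    instanceId <- tools::file_path_sans_ext(basename(path))
  }
  parsed <- tryCatch(
    switch(format,
      ply = parsePly(path),
      stl = parseStl(path),
      obj = parseObj(path)
    ),
    error = function(e) {
      stop(sprintf("failed to read '%s': %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  stopIf(nrow(parsed$vertices) < 4L,
    sprintf("degenerate mesh in '%s': fewer than 4 vertices", path)
  )
  stopIf(is.null(parsed$faces) || nrow(parsed$faces) < 4L,
    sprintf("degenerate mesh in '%s': fewer than 4 faces", path)
  )
  surfaceMesh(parsed$vertices, parsed$faces, instanceId = instanceId)
}

# ---- PLY ----

plyTypeSize <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

plyReadBin <- function(con, type, n) {
  sz <- plyTypeSize[[type]]
  stopIf(is.null(sz), sprintf("unsupported PLY type '%s'", type))
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !grepl("^u", type)
  out <- readBin(con, what = what, n = n, size = sz, signed = signed || sz >= 4L,
    endian = "little"
  )
  stopIf(length(out) < n, "truncated PLY payload")
  out
}

parsePly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  stopIf(!identical(trimws(magic), "ply"), "not a PLY file (missing 'ply' magic)")
  fmt <- NULL
  elements <- list()
  current <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    stopIf(length(line) == 0L, "truncated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      stopIf(is.null(current), "PLY property outside element")
      if (tok[2] == "list") {
        current$props[[length(current$props) + 1L]] <-
          list(kind = "list", countType = tok[3], valueType = tok[4], name = tok[5])
      } else {
        current$props[[length(current$props) + 1L]] <-
          list(kind = "scalar", type = tok[2], name = tok[3])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(current)) elements[[current$name]] <- current
      break
    }
  }
  stopIf(is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"),
    sprintf("unsupported PLY format '%s'", if (is.null(fmt)) "?" else fmt)
  )
  stopIf(!"vertex" %in% names(elements), "PLY file has no vertex element")

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 0L
    readElementAscii <- function(el) {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        stopIf(pos + i > length(txt), "truncated PLY payload")
        rows[[i]] <- as.numeric(strsplit(trimws(txt[pos + i]), "\\s+")[[1]])
      }
      pos <<- pos + el$count
      rows
    }
    out <- list()
    for (el in elements) out[[el$name]] <- readElementAscii(el)
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    vmat <- do.call(rbind, out$vertex)
    stopIf(!all(c("x", "y", "z") %in% vprops), "PLY vertex element lacks x/y/z")
    vertices <- vmat[, match(c("x", "y", "z"), vprops), drop = FALSE]
    faces <- NULL
    if ("face" %in% names(elements)) {
      faces <- do.call(rbind, lapply(out$face, function(r) {
        stopIf(r[1] != 3, "only triangulated PLY faces are supported")
        r[2:4] + 1L
      }))
    }
  } else {
    readElementBin <- function(el) {
      scalar <- all(vapply(el$props, `[[`, "", "kind") == "scalar")
      if (scalar) {
        types <- vapply(el$props, `[[`, "", "type")
        if (length(unique(types)) == 1L) {
          vals <- plyReadBin(con, types[1], el$count * length(types))
          return(matrix(vals, ncol = length(types), byrow = TRUE))
        }
        rows <- matrix(0, el$count, length(types))
        for (i in seq_len(el$count)) {
          for (j in seq_along(types)) rows[i, j] <- plyReadBin(con, types[j], 1L)
        }
        return(rows)
      }
      # list properties (faces): read row by row
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        row <- numeric(0)
        for (p in el$props) {
          if (p$kind == "scalar") {
            row <- c(row, plyReadBin(con, p$type, 1L))
          } else {
            cnt <- plyReadBin(con, p$countType, 1L)
            row <- c(row, cnt, plyReadBin(con, p$valueType, cnt))
          }
        }
        rows[[i]] <- row
      }
      rows
    }
    out <- list()
    for (el in elements) out[[el$name]] <- readElementBin(el)
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    stopIf(!all(c("x", "y", "z") %in% vprops), "PLY vertex element lacks x/y/z")
    vertices <- out$vertex[, match(c("x", "y", "z"), vprops), drop = FALSE]
    faces <- NULL
    if ("face" %in% names(elements)) {
      faces <- do.call(rbind, lapply(out$face, function(r) {
        stopIf(r[1] != 3, "only triangulated PLY faces are supported")
        r[2:4] + 1L
      }))
    }
  }
  list(vertices = vertices, faces = faces)
}

# ---- STL ----

parseStl <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  headTxt <- rawToChar(raw[seq_len(min(80L, length(raw)))])
  isAscii <- grepl("^\\s*solid", headTxt) &&
    grepl("facet", rawToChar(raw[seq_len(min(2048L, length(raw)))]), fixed = TRUE)
  if (isAscii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    stopIf(length(vl) == 0L || length(vl) %% 3L != 0L, "malformed ASCII STL")
    tri <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) as.numeric(t[2:4])))
  } else {
    stopIf(length(raw) < 84L, "truncated binary STL")
    nTri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    need <- 84L + 50L * nTri
    stopIf(length(raw) < need, "truncated binary STL")
    tri <- matrix(0, 3L * nTri, 3L)
    con <- rawConnection(raw[-(1:84)])
    on.exit(close(con))
    for (t in seq_len(nTri)) {
      vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      tri[(3L * t - 2L):(3L * t), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
      readBin(con, "raw", n = 2L)  # attribute byte count
    }
  }
  # weld exact-duplicate coordinates into shared vertices
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "/")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  vertices <- tri[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

# ---- OBJ ----

parseObj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[grepl("^v\\s", lines)]
  fl <- lines[grepl("^f\\s", lines)]
  stopIf(length(vl) == 0L, "OBJ file has no vertices")
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) {
    as.numeric(t[2:4])
  }))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t) {
    refs <- t[-1]
    stopIf(length(refs) != 3L, "only triangulated OBJ faces are supported")
    as.integer(vapply(strsplit(refs, "/"), `[[`, "", 1L))
  }))
  list(vertices = vertices, faces = faces)
}

#' Write a surface mesh
#'
#' Writes ASCII PLY, ASCII STL or OBJ, chosen by the file extension.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path ending in .ply, .stl or .obj.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  stopIf(!is(mesh, "SurfaceMesh"), "mesh must be a SurfaceMesh")
  ext <- tolower(tools::file_ext(path))
  v <- mesh@vertices
  f <- mesh@faces
  if (ext == "ply") {
    hdr <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      "property double nx", "property double ny", "property double nz",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header"
    )
    vn <- cbind(v, mesh@normals)
    body <- apply(vn, 1L, function(r) paste(format(r, digits = 17), collapse = " "))
    fb <- apply(f - 1L, 1L, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c(hdr, body, fb), path)
  } else if (ext == "obj") {
    vb <- apply(v, 1L, function(r) paste(c("v", format(r, digits = 17)), collapse = " "))
    fb <- apply(f, 1L, function(r) paste(c("f", r), collapse = " "))
    writeLines(c(vb, fb), path)
  } else if (ext == "stl") {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    fn <- normalizeRows(crossProduct(e1, e2))
    out <- c(sprintf("solid %s", mesh@instanceId))
    for (t in seq_len(nrow(f))) {
      out <- c(out,
        sprintf("facet normal %s", paste(format(fn[t, ], digits = 17), collapse = " ")),
        "  outer loop",
        sprintf("    vertex %s", apply(v[f[t, ], , drop = FALSE], 1L, function(r) {
          paste(format(r, digits = 17), collapse = " ")
        })),
        "  endloop",
        "endfacet"
      )
    }
    out <- c(out, sprintf("endsolid %s", mesh@instanceId))
    writeLines(out, path)
  } else {
    stop(sprintf("unsupported mesh output extension '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write a point cloud as ASCII PLY with normals
#'
#' @param cloud a [PointCloud-class].
#' @param path output .ply path.
#' @return `path`, invisibly.
#' @export
writePointCloud <- function(cloud, path) {
  stopIf(!is(cloud, "PointCloud"), "cloud must be a PointCloud")
  p <- cloud@points
  hasN <- nrow(cloud@normals) > 0L
  hdr <- c(
    "ply", "format ascii 1.0",
    if (!is.na(cloud@centroidSize)) {
      sprintf("comment centroid_size %.17g", cloud@centroidSize)
    },
    sprintf("element vertex %d", nrow(p)),
    "property double x", "property double y", "property double z"
  )
  if (hasN) {
    hdr <- c(hdr, "property double nx", "property double ny", "property double nz")
    p <- cbind(p, cloud@normals)
  }
  hdr <- c(hdr, "end_header")
  body <- apply(p, 1L, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a point cloud from a PLY file
#'
#' Reads the vertex element of a PLY file (faces, if any, are ignored)
#' together with nx/ny/nz normals when present. A `centroid_size` comment
#' written by [writePointCloud()] is restored.
#'
#' @param path a .ply path.
#' @param instanceId optional label (defaults to the file name).
#' @return a [PointCloud-class].
#' @export
readPointCloud <- function(path, instanceId = NULL) {
  stopIf(!file.exists(path), sprintf("cannot read point cloud: no such file '%s'", path))
  if (is.null(instanceId)) instanceId <- tools::file_path_sans_ext(basename(path))
  cs <- NA_real_
  hdr <- readLines(path, n = 200L)
  csLine <- grep("^comment centroid_size ", hdr, value = TRUE)
  if (length(csLine) > 0L) {
    csStr <- sub("^comment centroid_size ", "", csLine[1])
    cs <- if (csStr %in% c("NA", "NaN", "nan")) NA_real_ else as.numeric(csStr)
  }
  parsed <- parsePly(path)
  vprops <- parsed$vertices
  normals <- NULL
  # parsePly returns xyz only; re-read normals if declared (ASCII only)
  if (!any(grepl("format ascii", hdr, fixed = TRUE))) {
    return(pointCloud(vprops, centroidSize = cs, instanceId = instanceId))
  }
  raw <- readLines(path)
  endIdx <- which(trimws(raw) == "end_header")[1]
  props <- grep("^property ", raw[seq_len(endIdx)], value = TRUE)
  pnames <- vapply(strsplit(trimws(props), "\\s+"), function(t) t[length(t)], "")
  if (all(c("nx", "ny", "nz") %in% pnames)) {
    nV <- nrow(vprops)
    rows <- raw[(endIdx + 1L):(endIdx + nV)]
    vals <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    normals <- vals[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
  }
  pointCloud(vprops, normals = normals, centroidSize = cs, instanceId = instanceId)
}
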