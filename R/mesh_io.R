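#' Construct and validate a closed triangulated surface mesh
#'
#' A `surface_mesh` is the input object of the complexity pipeline: a
#' watertight, consistently wound triangle mesh whose enclosed volume
#' anchors the optimal-refinement search. Validation enforces
#' watertightness (every edge shared by exactly two faces), rejects
#' degenerate zero-area triangles, and normalizes the orientation so the
#' signed volume is non-negative. Non-watertight meshes are rejected, not
#' repaired: a silently hole-filled surface would bias the volume anchor
#' and hence the complexity score.
#'
#' @param vertices numeric matrix, one 3D coordinate per row.
#' @param faces integer matrix, one triangle per row as vertex-index
#'   triples (1-based).
#' @param units opaque unit tag carried through the pipeline (all derived
#'   quantities of interest are dimensionless).
#' @param validate if `FALSE`, skip checks (internal use on meshes known
#'   watertight by construction).
#' @return an object of class `surface_mesh` with fields `vertices`,
#'   `faces`, `units`.
#' @export
surface_mesh <- function(vertices, faces, units = "unitless", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3) stop("faces must be an m x 3 matrix of vertex triples")
  mesh <- structure(list(vertices = vertices, faces = faces, units = units),
                    class = "surface_mesh")
  if (validate) mesh <- validate_mesh(mesh)
  mesh
}

#' Validate a surface mesh
#'
#' Checks index bounds, watertightness, degenerate faces, and normalizes
#' winding so the signed volume is positive. Open meshes raise an error
#' naming the boundary edges, since every volume-dependent operation
#' refuses such input.
#'
#' @param mesh a `surface_mesh`.
#' @return the validated (possibly re-wound) mesh.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (any(!is.finite(v))) stop("mesh vertices contain non-finite coordinates")
  if (min(f) < 1L || max(f) > nrow(v))
    stop("face indices out of range: mesh refers to missing vertices")

  # degenerate faces: zero area relative to the mesh scale
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  scale <- max(apply(v, 2, function(x) diff(range(x))))
  if (any(area2 <= (1e-12 * scale)^2))
    stop("mesh contains degenerate (zero-area) faces: ",
         paste(utils::head(which(area2 <= (1e-12 * scale)^2), 5), collapse = ", "))

  # watertight: every undirected edge borders exactly two faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(edges[, 1], edges[, 2]) * 131072 + pmax(edges[, 1], edges[, 2])
  tab <- table(key)
  bad <- as.numeric(names(tab)[tab != 2])
  if (length(bad)) {
    b <- cbind(bad %/% 131072, bad %% 131072)
    stop("mesh is not watertight; ", length(bad), " boundary/non-manifold edge(s), e.g. ",
         paste(apply(utils::head(b, 5), 1, paste, collapse = "-"), collapse = ", "))
  }

  # consistent winding: every directed edge must appear exactly once
  dkey <- edges[, 1] * 131072 + edges[, 2]
  if (anyDuplicated(dkey))
    stop("mesh winding is inconsistent: a directed edge appears twice")

  # orient outward: flip all faces if signed volume is negative
  if (signed_volume(v, f) < 0) mesh$faces <- f[, c(1, 3, 2)]
  mesh
}

signed_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Sum of signed tetrahedron volumes (origin, v1, v2, v3) over all faces;
#' exact for watertight, consistently wound meshes and invariant to rigid
#' motion.
#'
#' @param mesh a validated `surface_mesh`.
#' @return enclosed volume (length units cubed).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  abs(signed_volume(mesh$vertices, mesh$faces))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, volume %.6g [%s^3]\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x), x$units))
  invisible(x)
}

#' Rigid and scaling transforms of a mesh
#'
#' Convenience helpers used when checking that complexity is invariant to
#' translation, rotation, and uniform scale.
#'
#' @param mesh a `surface_mesh`.
#' @param offset length-3 translation vector.
#' @param factor positive scalar scale factor.
#' @param R 3x3 rotation matrix.
#' @return the transformed mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

#' @rdname translate_mesh
#' @export
scale_mesh <- function(mesh, factor) {
  stopifnot(factor > 0)
  mesh$vertices <- mesh$vertices * factor
  mesh
}

#' @rdname translate_mesh
#' @export
rotate_mesh <- function(mesh, R) {
  stopifnot(all(dim(R) == c(3, 3)))
  mesh$vertices <- mesh$vertices %*% t(R)
  mesh
}

#' Random 3D rotation matrix
#'
#' Uniform over SO(3) via QR decomposition of a Gaussian matrix.
#'
#' @param seed optional integer seed.
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## ---------------------------------------------------------------------------
## File formats. Meshes arrive from photogrammetry exports as PLY/OBJ/STL;
## readers below accept ASCII OBJ/STL, ASCII and binary-little-endian PLY,
## and binary STL. Writers emit ASCII or binary PLY (with optional vertex
## colors) and OBJ.

#' Read a triangulated surface mesh from file
#'
#' Supports PLY (ASCII and binary little-endian), OBJ, and STL (ASCII and
#' binary); quads are not triangulated, and non-watertight meshes are
#' rejected at validation.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"obj"`, `"stl"`; `"auto"`
#'   dispatches on the file extension.
#' @param units unit tag to attach.
#' @return a validated `surface_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "stl"),
                      units = "unitless") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "obj", "stl"))
      stop("cannot infer mesh format from extension '", format, "'")
  }
  raw <- switch(format,
                ply = read_ply(path),
                obj = read_obj(path),
                stl = read_stl(path))
  surface_mesh(raw$vertices, raw$faces, units = units)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("not a parseable OBJ file: ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(x) {
    idx <- as.integer(vapply(strsplit(x, "/"), `[`, "", 1))
    if (length(idx) != 3) stop("OBJ contains non-triangular faces")
    idx
  }))
  list(vertices = verts, faces = faces)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("truncated PLY header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop("not a PLY file: ", path)
  fmt <- header[grepl("^format", header)][1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format (only ascii and binary_little_endian): ", fmt)

  elem_lines <- grep("^element", header)
  elems <- list()
  for (i in seq_along(elem_lines)) {
    parts <- strsplit(trimws(header[elem_lines[i]]), "\\s+")[[1]]
    to <- if (i < length(elem_lines)) elem_lines[i + 1] - 1 else length(header) - 1
    props <- header[(elem_lines[i] + 1):to]
    props <- props[grepl("^property", props)]
    elems[[parts[2]]] <- list(count = as.integer(parts[3]), props = props)
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY lacks vertex/face elements")

  ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                     short = 2, ushort = 2, int16 = 2, uint16 = 2,
                     int = 4, uint = 4, int32 = 4, uint32 = 4,
                     float = 4, float32 = 4, double = 8, float64 = 8)

  if (binary) {
    nv <- elems$vertex$count
    vp <- strsplit(trimws(elems$vertex$props), "\\s+")
    vtypes <- vapply(vp, `[`, "", 2)
    vnames <- vapply(vp, `[`, "", 3)
    vert <- matrix(NA_real_, nv, length(vnames))
    for (i in seq_len(nv)) {
      for (j in seq_along(vtypes)) {
        sz <- ply_type_size[[vtypes[j]]]
        what <- if (vtypes[j] %in% c("float", "float32", "double", "float64"))
          "double" else "integer"
        vert[i, j] <- readBin(con, what, 1, size = sz, endian = "little",
                              signed = !(vtypes[j] %in% c("uchar", "uint8", "ushort", "uint16")))
      }
    }
    colnames(vert) <- vnames
    fp <- strsplit(trimws(elems$face$props[1]), "\\s+")[[1]]
    cnt_t <- fp[3]; idx_t <- fp[4]
    faces <- matrix(NA_integer_, elems$face$count, 3)
    for (i in seq_len(elems$face$count)) {
      n <- readBin(con, "integer", 1, size = ply_type_size[[cnt_t]],
                   endian = "little", signed = FALSE)
      idx <- readBin(con, "integer", n, size = ply_type_size[[idx_t]],
                     endian = "little")
      if (n != 3) stop("PLY contains non-triangular faces")
      faces[i, ] <- idx + 1L
    }
    return(list(vertices = vert[, c("x", "y", "z")], faces = faces))
  }

  body <- readLines(con, warn = FALSE)
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$count
  nf <- elems$face$count
  vp <- strsplit(trimws(elems$vertex$props), "\\s+")
  vnames <- vapply(vp, `[`, "", 3)
  vert <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                as.numeric))
  colnames(vert) <- vnames
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                 function(x) {
    x <- as.integer(x)
    if (x[1] != 3) stop("PLY contains non-triangular faces")
    x[2:4] + 1L
  }))
  list(vertices = vert[, c("x", "y", "z")], faces = faces)
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", 84)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") &&
    grepl("facet", paste(readLines(path, n = 20, warn = FALSE), collapse = " "))
  tri <- if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- trimws(lines[grepl("^\\s*vertex", lines)])
    do.call(rbind, lapply(strsplit(vl, "\\s+"),
                          function(x) as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    out <- matrix(NA_real_, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", 12, size = 4, endian = "little")
      out[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
    out
  }
  # STL stores soup triangles: merge coincident vertices exactly
  key <- apply(tri, 1, function(p) paste(sprintf("%.17g", p), collapse = ","))
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(uid), , drop = FALSE]
  list(vertices = verts, faces = matrix(uid, ncol = 3, byrow = TRUE))
}

#' Write a surface mesh to file
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"ply"` or `"obj"`.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @param vertex_colors optional n x 3 integer matrix of RGB values
#'   (0-255), PLY only.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "obj"), binary = FALSE,
                       vertex_colors = NULL) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    return(invisible(path))
  }
  has_col <- !is.null(vertex_colors)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    for (i in seq_len(nrow(v))) {
      writeBin(as.numeric(v[i, ]), con, size = 8, endian = "little")
      if (has_col) writeBin(as.raw(vertex_colors[i, ]), con)
    }
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (has_col) {
      writeLines(sprintf("%.17g %.17g %.17g %d %d %d",
                         v[, 1], v[, 2], v[, 3], vertex_colors[, 1],
                         vertex_colors[, 2], vertex_colors[, 3]), con)
    } else {
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    }
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' Write a complexity heatmap mesh with vertex colors
#'
#' Writes the boundary surface of the optimal-refinement alpha shape as a
#' PLY with per-vertex RGB colors (warm = low coarsest-k = complex,
#' cool = high coarsest-k = simple) plus sidecar CSVs holding the raw
#' per-vertex and per-face coarsest refinement coefficients at full
#' precision (bit-exact on re-read).
#'
#' @param hm a `heatmap_mesh` from [build_heatmap()].
#' @param path output PLY path; sidecars get `_vertex_k.csv` and
#'   `_face_k.csv` suffixes on the stem.
#' @return invisibly, a list with the three paths written.
#' @export
write_heatmap_mesh <- function(hm, path) {
  stopifnot(inherits(hm, "heatmap_mesh"))
  cols <- k_to_color(hm$vertex_k, hm$k_grid)
  mesh <- list(vertices = hm$vertices, faces = hm$faces)
  write_mesh(structure(mesh, class = "surface_mesh"), path, format = "ply",
             vertex_colors = cols)
  stem <- sub("\\.ply$", "", path)
  vpath <- paste0(stem, "_vertex_k.csv")
  fpath <- paste0(stem, "_face_k.csv")
  vcon <- file(vpath, "w")
  writeLines(c("vertex_id,coarsest_k",
               sprintf("%d,%.17g", seq_len(nrow(hm$vertices)), hm$vertex_k)), vcon)
  close(vcon)
  fcon <- file(fpath, "w")
  writeLines(c("face_id,face_k",
               sprintf("%d,%.17g", seq_len(nrow(hm$faces)), hm$face_k)), fcon)
  close(fcon)
  invisible(list(ply = path, vertex_csv = vpath, face_csv = fpath))
}

#' Read/write point clouds as XYZ text
#'
#' One point per line, whitespace-separated, full double precision.
#'
#' @param points n x 3 matrix.
#' @param path file path.
#' @return `write_xyz` the path invisibly; `read_xyz` an n x 3 matrix.
#' @export
write_xyz <- function(points, path) {
  writeLines(sprintf("%.17g %.17g %.17g", points[, 1], points[, 2], points[, 3]),
             path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  as.matrix(read.table(path, col.names = c("x", "y", "z")))
}
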