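#' Triangulated surface mesh
#'
#' A minimal container for triangulated boundary surfaces: an `n x 3` matrix
#' of vertex coordinates in millimetres and an `m x 3` integer matrix of
#' 1-based triangle indices. Triangles are consistently wound so that normals
#' point outward (enclosed volume positive).
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas via the cross product.
#'
#' @param mesh a [surface_mesh()].
#' @return Surface area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  tri_a <- triangle_areas(mesh)
  if (length(tri_a) == 0L || sum(tri_a) <= 0)
    stop("degenerate mesh: zero total surface area")
  sum(tri_a)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  a <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - a
  w <- v[f[, 3L], , drop = FALSE] - a
  cx <- u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L]
  cy <- u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L]
  cz <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem signed volume (sum of signed tetrahedra against the
#' origin); positive for outward-wound closed surfaces. Raises an error if
#' the mesh is not closed (some edge is not shared by exactly two triangles).
#'
#' @param mesh a [surface_mesh()].
#' @return Signed volume in mm^3.
#' @export
mesh_enclosed_volume <- function(mesh) {
  if (!mesh_is_closed(mesh)) stop("mesh is not closed")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
    a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
    a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  sum(det6) / 6
}

#' Test whether every mesh edge is shared by exactly two triangles
#'
#' @param mesh a [surface_mesh()].
#' @return `TRUE` if the mesh is closed (watertight), else `FALSE`.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Apply an affine map to mesh vertices
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3x3 matrix applied on the right of the vertex rows.
#' @param translation length-3 offset added after rotation.
#' @return The transformed mesh; winding is flipped automatically when the
#'   linear part inverts orientation (negative determinant), so outward
#'   normals are preserved under mirroring.
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2L, translation, "+")
  f <- mesh$faces
  if (det(rotation) < 0) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  surface_mesh(v, f)
}

#' Mirror a mesh across a coordinate plane
#'
#' @param mesh a [surface_mesh()].
#' @param axis axis index (1 = medio-lateral) whose coordinate is negated.
#' @return Mirrored mesh with corrected winding.
#' @export
mesh_mirror <- function(mesh, axis = 1L) {
  r <- diag(3)
  r[axis, axis] <- -1
  mesh_transform(mesh, rotation = r)
}

# --- mesh file IO (ASCII PLY and OBJ) --------------------------------------

#' Write a mesh to an ASCII PLY or OBJ file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; format chosen by extension (`.ply` or `.obj`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "wb") # binary connection: fixed LF line endings
    on.exit(close(con))
    hdr <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header"
    )
    writeLines(hdr, con)
    writeLines(sprintf("%.8g %.8g %.8g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  } else if (ext == "obj") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(sprintf("v %.8g %.8g %.8g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}

#' Read a mesh from an ASCII PLY or OBJ file
#'
#' Supports the subset written by [write_mesh()]: ASCII PLY with xyz vertex
#' properties and triangular faces, or OBJ `v`/`f` lines.
#'
#' @param path input path.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    if (lines[1L] != "ply" || !any(grepl("^format ascii", lines)))
      stop("only ASCII PLY is supported")
    end <- match("end_header", lines)
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1L]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1L]))
    vl <- lines[(end + 1L):(end + nv)]
    fl <- lines[(end + nv + 1L):(end + nv + nf)]
    v <- matrix(as.numeric(unlist(strsplit(vl, " +"))), ncol = 3L, byrow = TRUE)
    fparts <- matrix(as.integer(unlist(strsplit(fl, " +"))), ncol = 4L, byrow = TRUE)
    if (any(fparts[, 1L] != 3L)) stop("non-triangular face in PLY")
    surface_mesh(v, fparts[, 2:4] + 1L)
  } else if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " +"))), ncol = 3L, byrow = TRUE)
    f <- matrix(as.integer(unlist(strsplit(sub("^f ", "", fl), " +"))), ncol = 3L, byrow = TRUE)
    surface_mesh(v, f)
  } else {
    stop("unsupported mesh format: ", ext)
  }
}
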