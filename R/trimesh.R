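#' Watertight triangle mesh
#'
#' Container for the triangle surfaces that carry all bone and body-segment
#' geometry. Vertices are 3D points in meters; faces are vertex-index triples
#' oriented consistently outward. On construction the mesh is validated
#' (watertightness, no degenerate faces) and its orientation normalized so the
#' enclosed signed volume is positive.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (m).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param validate check watertightness and face quality (default `TRUE`).
#' @param normalize flip face winding if the signed volume is negative
#'   (default `TRUE`); a note is emitted via `message()` when this happens.
#' @return An object of class `"trimesh"` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- box_mesh(c(1, 1, 1))
#' mesh_volume(m)
#' @export
trimesh <- function(vertices, faces, validate = TRUE, normalize = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) < 4L) stop("a closed surface needs at least 4 faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")

  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "trimesh")
  if (validate) {
    dg <- degenerate_faces(mesh)
    if (length(dg) > 0L)
      stop("degenerate (zero-area) faces at rows: ",
           paste(utils::head(dg, 10L), collapse = ", "))
    open <- open_edges(mesh)
    if (nrow(open) > 0L) {
      shown <- utils::head(open, 10L)
      stop("mesh is not watertight; open or over-shared edges: ",
           paste(sprintf("(%d-%d)", shown[, 1L], shown[, 2L]), collapse = " "))
    }
  }
  if (normalize && mesh_signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
    message("trimesh: inward orientation detected; face winding flipped")
  }
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces, volume %.6g m^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_signed_volume(x)))
  invisible(x)
}

# Edges not shared by exactly two faces (undirected). Watertight iff empty.
open_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  bad <- names(tab)[tab != 2L]
  if (length(bad) == 0L)
    return(matrix(integer(0), 0L, 2L))
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

degenerate_faces <- function(mesh, rel_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  area2 <- sqrt(rowSums(cr^2))
  scale <- max(1, max(abs(v)))^2
  which(area2 <= rel_tol * scale)
}

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem sum of signed origin tetrahedra; positive for an
#' outward-oriented closed surface.
#'
#' @param mesh a [trimesh()].
#' @return Signed volume (m^3).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
          a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
          a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  sum(det3) / 6
}

#' @rdname mesh_signed_volume
#' @export
mesh_volume <- function(mesh) abs(mesh_signed_volume(mesh))

#' Apply a rigid (or general affine) transform to a mesh
#'
#' @param mesh a [trimesh()].
#' @param transform 4 x 4 homogeneous transform matrix.
#' @return Transformed `trimesh` (no re-validation; rigid motions preserve
#'   watertightness).
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(is.matrix(transform), all(dim(transform) == c(4L, 4L)))
  v <- cbind(mesh$vertices, 1) %*% t(transform)
  out <- mesh
  out$vertices <- v[, 1:3, drop = FALSE]
  out
}

#' Axis-aligned box mesh
#'
#' 12-triangle closed box, outward-oriented. Handy as a bone proxy and in
#' collision tests.
#'
#' @param size length-3 vector of edge lengths (m).
#' @param center box center (default origin).
#' @return A [trimesh()].
#' @export
box_mesh <- function(size = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- t(t(as.matrix(s) * rep(h, each = 8L)) + center)
  # vertex order: (-,-,-)(+,-,-)(-,+,-)(+,+,-)(-,-,+)(+,-,+)(-,+,+)(+,+,+)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z-)
    c(5, 6, 7), c(6, 8, 7),   # top (z+)
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  trimesh(v, f, validate = FALSE, normalize = TRUE)
}

#' Subdivided icosahedron sphere mesh
#'
#' @param radius sphere radius (m).
#' @param subdivisions number of 4-to-1 triangle subdivisions (4 gives 5120
#'   faces, volume within 0.1% of the analytic sphere).
#' @param center sphere center.
#' @return A [trimesh()].
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    n <- nrow(v)
    edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_id(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- n + length(newv)
      mids[[k]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (j in seq_len(nrow(f))) {
      a <- f[j, 1L]; b <- f[j, 2L]; c3 <- f[j, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(j - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- t(t(v * radius) + center)
  trimesh(v, f, validate = FALSE, normalize = TRUE)
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records; polygonal faces are fan-triangulated on load.
#' Texture/normal indices in face records (`a/b/c` syntax) are ignored.
#'
#' @param path OBJ file path.
#' @param scale multiplicative scale applied to coordinates (files are assumed
#'   meters unless a scale is supplied).
#' @param validate passed to [trimesh()].
#' @return A [trimesh()].
#' @export
read_obj <- function(path, scale = 1, validate = TRUE) {
  if (!file.exists(path)) stop("OBJ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L || length(fl) == 0L)
    stop("no vertex/face records in OBJ: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3]))) * scale
  tri <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
    if (length(idx) < 3L) stop("face with fewer than 3 vertices in ", path)
    for (k in 2:(length(idx) - 1L))
      tri[[length(tri) + 1L]] <- c(idx[1L], idx[k], idx[k + 1L])
  }
  trimesh(v, do.call(rbind, tri), validate = validate)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangulated mesh, units meters", con)
  writeLines(sprintf("v %.12g %.12g %.12g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]),
             con)
  invisible(path)
}
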