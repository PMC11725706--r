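# Triangle-triangle mesh intersection, used by the ROM scanner as the bone
# collision proxy. Interval-overlap method on the line of intersection of
# the two triangle planes; coplanar pairs fall back to a 2D overlap test.
# Axis-aligned bounding boxes prefilter candidate pairs.

#' Do two meshes intersect?
#'
#' @param mesh_a,mesh_b [trimesh()] objects, already posed.
#' @param exclude_a,exclude_b face-row indices to skip (articular patches).
#' @param tol contact tolerance; separations smaller than this count as
#'   touching, not intersecting (grazing contact is admissible).
#' @return `TRUE` if any triangle pair properly intersects.
#' @export
meshes_intersect <- function(mesh_a, mesh_b, exclude_a = integer(0),
                             exclude_b = integer(0), tol = 1e-9) {
  fa <- if (length(exclude_a)) mesh_a$faces[-exclude_a, , drop = FALSE]
        else mesh_a$faces
  fb <- if (length(exclude_b)) mesh_b$faces[-exclude_b, , drop = FALSE]
        else mesh_b$faces
  va <- mesh_a$vertices
  vb <- mesh_b$vertices
  if (nrow(fa) == 0L || nrow(fb) == 0L) return(FALSE)
  box <- function(v, f) {
    x <- matrix(v[t(f), 1L], 3L); y <- matrix(v[t(f), 2L], 3L)
    z <- matrix(v[t(f), 3L], 3L)
    cbind(apply(x, 2L, min), apply(x, 2L, max),
          apply(y, 2L, min), apply(y, 2L, max),
          apply(z, 2L, min), apply(z, 2L, max))
  }
  ba <- box(va, fa); bb <- box(vb, fb)
  # global AABB rejection
  if (any(apply(ba[, c(1, 3, 5), drop = FALSE], 2L, min) >
          apply(bb[, c(2, 4, 6), drop = FALSE], 2L, max) + tol) ||
      any(apply(bb[, c(1, 3, 5), drop = FALSE], 2L, min) >
          apply(ba[, c(2, 4, 6), drop = FALSE], 2L, max) + tol))
    return(FALSE)
  for (i in seq_len(nrow(fa))) {
    cand <- which(bb[, 1L] <= ba[i, 2L] + tol & bb[, 2L] >= ba[i, 1L] - tol &
                  bb[, 3L] <= ba[i, 4L] + tol & bb[, 4L] >= ba[i, 3L] - tol &
                  bb[, 5L] <= ba[i, 6L] + tol & bb[, 6L] >= ba[i, 5L] - tol)
    if (length(cand) == 0L) next
    t1 <- va[fa[i, ], , drop = FALSE]
    for (jj in cand) {
      t2 <- vb[fb[jj, ], , drop = FALSE]
      if (tri_tri_intersect(t1, t2, tol)) return(TRUE)
    }
  }
  FALSE
}

tri_tri_intersect <- function(t1, t2, tol = 1e-9) {
  n2 <- cross3(t2[2L, ] - t2[1L, ], t2[3L, ] - t2[1L, ])
  d1 <- as.numeric((t1 - matrix(t2[1L, ], 3L, 3L, byrow = TRUE)) %*% n2)
  scale2 <- sqrt(sum(n2^2))
  if (scale2 < tol) return(FALSE)        # degenerate triangle
  d1 <- d1 / scale2
  if (all(d1 > tol) || all(d1 < -tol)) return(FALSE)

  n1 <- cross3(t1[2L, ] - t1[1L, ], t1[3L, ] - t1[1L, ])
  d2 <- as.numeric((t2 - matrix(t1[1L, ], 3L, 3L, byrow = TRUE)) %*% n1)
  scale1 <- sqrt(sum(n1^2))
  if (scale1 < tol) return(FALSE)
  d2 <- d2 / scale1
  if (all(d2 > tol) || all(d2 < -tol)) return(FALSE)

  if (all(abs(d1) <= tol) && all(abs(d2) <= tol))
    return(coplanar_tri_overlap(t1, t2, n1 / scale1, tol))

  D <- cross3(n1, n2)
  axis <- which.max(abs(D))
  i1 <- tri_line_interval(t1[, axis], d1, tol)
  i2 <- tri_line_interval(t2[, axis], d2, tol)
  if (is.null(i1) || is.null(i2)) return(FALSE)
  max(i1[1L], i2[1L]) < min(i1[2L], i2[2L]) - tol
}

# Projected interval of a triangle on the plane-intersection line, from the
# projections p (onto a coordinate axis of the line) and signed distances d
# to the other triangle's plane.
tri_line_interval <- function(p, d, tol) {
  pts <- numeric(0)
  for (a in 1:3) for (b in 1:3) {
    if (a >= b) next
    if ((d[a] > tol && d[b] < -tol) || (d[a] < -tol && d[b] > tol)) {
      t <- d[a] / (d[a] - d[b])
      pts <- c(pts, p[a] + t * (p[b] - p[a]))
    }
  }
  on_plane <- abs(d) <= tol
  pts <- c(pts, p[on_plane])
  if (length(pts) < 2L) return(NULL)
  range(pts)
}

coplanar_tri_overlap <- function(t1, t2, n, tol) {
  basis <- complete_basis(n)
  p1 <- t1 %*% basis
  p2 <- t2 %*% basis
  for (a in 1:3) for (b in 1:3) {
    if (segments_cross(p1[a, ], p1[a %% 3L + 1L, ],
                       p2[b, ], p2[b %% 3L + 1L, ]))
      return(TRUE)
  }
  point_in_tri2(p1[1L, ], p2, tol) || point_in_tri2(p2[1L, ], p1, tol)
}

point_in_tri2 <- function(p, tri, tol) {
  s <- vapply(1:3, function(k)
    cross2(tri[k %% 3L + 1L, ] - tri[k, ], p - tri[k, ]), 0)
  all(s >= -tol) || all(s <= tol)
}
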