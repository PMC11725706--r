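# Homogeneous-transform helpers shared by kinematics, muscles and mass code.
# Convention: 4 x 4 matrices, column vectors, global frame +X craniad,
# +Y left, +Z dorsad. Angles are degrees at every public interface and
# radians internally.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

rot_x <- function(deg) {
  t <- deg2rad(deg); c3 <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c3, s, 0, -s, c3), 3, 3)
}
rot_y <- function(deg) {
  t <- deg2rad(deg); c3 <- cos(t); s <- sin(t)
  matrix(c(c3, 0, -s, 0, 1, 0, s, 0, c3), 3, 3)
}
rot_z <- function(deg) {
  t <- deg2rad(deg); c3 <- cos(t); s <- sin(t)
  matrix(c(c3, s, 0, -s, c3, 0, 0, 0, 1), 3, 3)
}

#' Intrinsic x-y-z Euler rotation matrix
#'
#' Rotation applied in x, then y, then z axis order: `R = Rx %*% Ry %*% Rz`,
#' the joint-rotation convention used throughout the kinematic model.
#'
#' @param angles_deg length-3 vector `(x, y, z)` of angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_xyz <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3L)
  rot_x(angles_deg[1L]) %*% rot_y(angles_deg[2L]) %*% rot_z(angles_deg[3L])
}

#' Build a homogeneous rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 translation (default zero).
#' @return 4 x 4 homogeneous matrix.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  out <- diag(4)
  out[1:3, 1:3] <- rotation
  out[1:3, 4L] <- translation
  out
}

is_rigid <- function(transform, tol = 1e-8) {
  R <- transform[1:3, 1:3]
  max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < tol &&
    all(transform[4L, ] == c(0, 0, 0, 1))
}

apply_transform <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  out <- cbind(points, 1) %*% t(transform)
  out[, 1:3, drop = FALSE]
}

# Gram-Schmidt completion of a right-handed frame from a primary axis and a
# reference direction; columns are x, y, z with `primary` placed in the slot
# named by `primary_axis`.
frame_from_axes <- function(primary, reference, primary_axis = "z") {
  pz <- primary / sqrt(sum(primary^2))
  r <- reference - sum(reference * pz) * pz
  nr <- sqrt(sum(r^2))
  if (nr < 1e-12)
    stop("reference direction is parallel to the primary axis")
  px <- r / nr
  py <- cross3(pz, px)
  ax <- switch(primary_axis,
               z = cbind(px, py, pz),
               x = cbind(pz, px, py),
               y = cbind(py, pz, px),
               stop("primary_axis must be one of x, y, z"))
  dimnames(ax) <- NULL
  ax
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Deterministic sign convention for fitted direction vectors: positive dot
# with +X, ties broken by +Y then +Z.
canonical_sign <- function(u, tol = 1e-12) {
  for (i in 1:3) {
    if (u[i] > tol) return(u)
    if (u[i] < -tol) return(-u)
  }
  u
}
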