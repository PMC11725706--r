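#' Fit a geometric primitive to an articular-surface point patch
#'
#' Least-squares fits of the primitive kinds used to derive anatomical
#' coordinate systems from articular surfaces: cylinders (vertebral centra
#' and distal ends of limb bones), spheres (glenoid, proximal humerus,
#' radius/ulna ends), an ellipsoid (proximal femur) and planes (proximal
#' ends of limb bones). Direction vectors (cylinder axis, plane normal,
#' ellipsoid axes) are returned as unit vectors with a deterministic sign:
#' positive dot product with +X, ties broken by +Y then +Z.
#'
#' @param points n x 3 matrix of surface samples (m).
#' @param kind one of `"sphere"`, `"cylinder"`, `"ellipsoid"`, `"plane"`.
#' @return Object of class `"primitive_fit"` with fields depending on kind:
#'   `center` and `radius` (sphere); `center`, `axis`, `radius` (cylinder);
#'   `center`, `axes` (columns, longest first), `radii` (ellipsoid);
#'   `center`, `normal` (plane). All carry `rms`, the root-mean-square
#'   orthogonal residual (m), and `n`.
#' @examples
#' pts <- make_articular_patch(list(kind = "sphere", center = c(1, 2, 3),
#'                                  radius = 0.05), n = 50, sigma = 0, seed = 1)
#' fit_primitive(pts, "sphere")$radius
#' @export
fit_primitive <- function(points, kind = c("sphere", "cylinder", "ellipsoid",
                                           "plane")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  storage.mode(points) <- "double"
  n <- nrow(points)
  fit <- switch(kind,
    plane = fit_plane(points),
    sphere = fit_sphere(points),
    cylinder = fit_cylinder(points),
    ellipsoid = fit_ellipsoid(points))
  fit$kind <- kind
  fit$n <- n
  class(fit) <- "primitive_fit"
  fit
}

#' @export
print.primitive_fit <- function(x, ...) {
  cat(sprintf("%s fit to %d points, RMS residual %.3g m\n",
              x$kind, x$n, x$rms))
  invisible(x)
}

fit_plane <- function(p) {
  if (nrow(p) < 3L) stop("plane fit needs >= 3 points")
  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  eg <- eigen(crossprod(pc) / nrow(p), symmetric = TRUE)
  if (eg$values[2L] <= 1e-12 * max(eg$values[1L], 1))
    stop("plane fit needs >= 3 non-collinear points")
  normal <- canonical_sign(eg$vectors[, 3L])
  d <- as.numeric(pc %*% normal)
  list(center = ctr, normal = normal, rms = sqrt(mean(d^2)))
}

fit_sphere <- function(p) {
  if (nrow(p) < 4L) stop("sphere fit needs >= 4 points")
  A <- cbind(2 * p, 1)
  y <- rowSums(p^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4L)
    stop("sphere fit needs >= 4 non-coplanar points")
  beta <- qr.coef(qr_A, y)
  ctr <- beta[1:3]
  r2 <- beta[4L] + sum(ctr^2)
  if (r2 <= 0) stop("degenerate sphere fit (non-positive radius)")
  r <- sqrt(r2)
  d <- sqrt(rowSums(sweep(p, 2L, ctr)^2)) - r
  list(center = unname(ctr), radius = unname(r), rms = sqrt(mean(d^2)))
}

# Axis direction optimized over spherical angles; for a candidate axis the
# points are projected onto the perpendicular plane and a circle is fitted
# algebraically (Kasa), scored by geometric residual. Multiple deterministic
# starts from the covariance eigenvectors.
fit_cylinder <- function(p) {
  if (nrow(p) < 6L) stop("cylinder fit needs >= 6 points")
  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  eg <- eigen(crossprod(pc), symmetric = TRUE)
  if (eg$values[2L] <= 1e-10 * max(eg$values[1L], 1))
    stop("cylinder fit needs non-collinear points")

  circle_resid <- function(axis) {
    axis <- axis / sqrt(sum(axis^2))
    basis <- complete_basis(axis)
    q <- pc %*% basis          # 2D coordinates in the perpendicular plane
    A <- cbind(2 * q, 1)
    beta <- tryCatch(qr.coef(qr(A), rowSums(q^2)), error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) return(list(rss = Inf))
    c2 <- unname(beta[1:2])
    r2 <- beta[3L] + sum(c2^2)
    if (r2 <= 0) return(list(rss = Inf))
    r <- sqrt(r2)
    d <- sqrt(rowSums(sweep(q, 2L, c2)^2)) - r
    list(rss = sum(d^2), center2 = c2, radius = r, basis = basis)
  }
  obj <- function(ang) {
    axis <- sph_dir(ang)
    circle_resid(axis)$rss
  }
  best <- NULL
  for (k in 1:3) {
    a0 <- eg$vectors[, k]
    ang0 <- c(acos(max(-1, min(1, a0[3L]))), atan2(a0[2L], a0[1L]))
    op <- stats::optim(ang0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || op$value < best$value) best <- op
  }
  axis <- canonical_sign(sph_dir(best$par))
  cr <- circle_resid(axis)
  center <- ctr + cr$basis %*% cr$center2   # mean axial station on the axis
  list(center = as.numeric(center), axis = axis,
       radius = unname(cr$radius), rms = sqrt(cr$rss / nrow(p)))
}

sph_dir <- function(ang) {
  c(sin(ang[1L]) * cos(ang[2L]), sin(ang[1L]) * sin(ang[2L]), cos(ang[1L]))
}

# Two unit vectors spanning the plane perpendicular to `axis` (3 x 2).
complete_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  h <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(axis, h); u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  cbind(u, v)
}

fit_ellipsoid <- function(p) {
  if (nrow(p) < 9L) stop("ellipsoid fit needs >= 9 points")
  x <- p[, 1L]; y <- p[, 2L]; z <- p[, 3L]
  # scale for conditioning
  ctr0 <- colMeans(p)
  sc <- max(apply(p, 2L, stats::sd), 1e-12)
  ps <- sweep(p, 2L, ctr0) / sc
  x <- ps[, 1L]; y <- ps[, 2L]; z <- ps[, 3L]
  D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z, 1)
  sv <- svd(D)
  if (sv$d[9L] <= 1e-10 * sv$d[1L])
    stop("degenerate ellipsoid fit (points do not constrain a quadric)")
  beta <- sv$v[, 10L]
  Q <- matrix(c(beta[1L], beta[4L] / 2, beta[5L] / 2,
                beta[4L] / 2, beta[2L], beta[6L] / 2,
                beta[5L] / 2, beta[6L] / 2, beta[3L]), 3, 3)
  b <- beta[7:9]
  d0 <- beta[10L]
  qc <- tryCatch(solve(Q, -b / 2), error = function(e)
    stop("degenerate ellipsoid fit (singular quadratic form)"))
  k <- as.numeric(t(qc) %*% Q %*% qc + sum(b * qc) + d0)
  M <- Q / (-k)
  eg <- eigen(M, symmetric = TRUE)
  if (any(eg$values <= 0))
    stop("fitted quadric is not an ellipsoid")
  radii_s <- 1 / sqrt(eg$values)          # scaled units
  ord <- order(radii_s, decreasing = TRUE)
  radii <- radii_s[ord] * sc
  axes <- eg$vectors[, ord, drop = FALSE]
  for (j in 1:3) axes[, j] <- canonical_sign(axes[, j])
  center <- ctr0 + qc * sc
  # approximate geometric residual: radial scaling error times local radius
  pc <- sweep(p, 2L, center)
  qv <- rowSums((pc %*% axes)^2 / rep(radii^2, each = nrow(pc)))
  rloc <- sqrt(rowSums(pc^2))
  d <- (sqrt(qv) - 1) * rloc
  list(center = as.numeric(center), axes = axes, radii = radii,
       rms = sqrt(mean(d^2)))
}

#' Build a right-handed anatomical coordinate system from a primitive
#'
#' The primary axis comes from the fitted primitive (cylinder axis or plane
#' normal; the longest principal axis for an ellipsoid; spheres have no
#' intrinsic axis, so `primary` must be supplied). The secondary axis is the
#' reference direction orthogonalized against the primary (Gram-Schmidt);
#' the third completes a right-handed orthonormal frame (det +1).
#'
#' @param primitive a `"primitive_fit"`.
#' @param reference unit reference direction, not parallel to the primary
#'   axis.
#' @param primary explicit primary axis; required for spheres, overrides the
#'   fitted axis otherwise.
#' @param primary_axis which JCS axis the primary maps to: `"z"` (default;
#'   flexion-extension), `"x"` (long-axis rotation) or `"y"`.
#' @return Object of class `"acs"`: `origin` (3-vector) and `axes`
#'   (3 x 3 orthonormal, columns x, y, z, determinant +1).
#' @export
build_acs <- function(primitive, reference, primary = NULL,
                      primary_axis = "z") {
  stopifnot(inherits(primitive, "primitive_fit"))
  if (is.null(primary)) {
    primary <- switch(primitive$kind,
      cylinder = primitive$axis,
      plane = primitive$normal,
      ellipsoid = primitive$axes[, 1L],
      sphere = stop("a sphere has no intrinsic axis; supply `primary`"))
  }
  axes <- frame_from_axes(primary, reference, primary_axis)
  structure(list(origin = as.numeric(primitive$center), axes = axes),
            class = "acs")
}

#' @export
print.acs <- function(x, ...) {
  cat("ACS origin (m):", sprintf("%.6g", x$origin), "\n")
  cat("axes (columns x, y, z):\n")
  print(signif(x$axes, 6))
  invisible(x)
}
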