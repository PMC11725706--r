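#' Muscle-tendon path
#'
#' An ordered polyline of attachment and via points, each bound to a
#' segment, plus optional wrapping surfaces that deflect the path. The
#' first point is the origin, the last the insertion. One per reconstructed
#' muscle; acronyms follow crocodylian nomenclature (IT1..AHD).
#'
#' @param acronym unique muscle acronym.
#' @param points data frame with columns `x`, `y`, `z` (m, reference pose)
#'   and `segment`; at least two rows.
#' @param wraps list of [wrap_surface()] objects.
#' @param inference optional origin/insertion inference levels (metadata,
#'   e.g. `c("I", "II'")`).
#' @return Object of class `"muscle_path"`.
#' @export
muscle_path <- function(acronym, points, wraps = list(), inference = NULL) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z", "segment") %in% names(points)))
    stop("points needs columns x, y, z, segment")
  if (nrow(points) < 2L) stop("a muscle path needs >= 2 points")
  structure(list(acronym = acronym, points = points, wraps = wraps,
                 inference = inference),
            class = "muscle_path")
}

#' Muscle wrapping surface
#'
#' Sphere or cylinder obstacle bound to a segment. A straight path segment
#' that penetrates the surface is replaced by the shortest tangent-arc-
#' tangent route over it; cylinder wrapping is solved in the plane
#' perpendicular to the axis and developed to 3D. Grazing tangency counts
#' as not wrapped, so path length is continuous across the engagement
#' boundary.
#'
#' @param kind `"sphere"` or `"cylinder"`.
#' @param segment segment the surface is bound to.
#' @param origin surface center / a point on the cylinder axis (m,
#'   reference pose).
#' @param radius surface radius (m), > 0.
#' @param axis cylinder axis direction (ignored for spheres).
#' @param side `"short"` (default: shorter wrap direction) or `"long"`
#'   (active-arc flag forcing the far-side arc on a cylinder).
#' @return Object of class `"wrap_surface"`.
#' @export
wrap_surface <- function(kind = c("sphere", "cylinder"), segment, origin,
                         radius, axis = c(0, 0, 1), side = "short") {
  kind <- match.arg(kind)
  if (radius <= 0) stop("wrap radius must be > 0")
  side <- match.arg(side, c("short", "long"))
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = kind, segment = segment, origin = as.numeric(origin),
                 radius = radius, axis = as.numeric(axis), side = side),
            class = "wrap_surface")
}

#' Length of a muscle-tendon path in a pose
#'
#' Sum of straight distances between consecutive posed path points, with
#' any straight span that penetrates an assigned wrap surface replaced by
#' the tangent-arc-tangent geodesic over it.
#'
#' @param muscle a [muscle_path()] or a muscle name in `model`.
#' @param model a [body_model()].
#' @param pose named pose list (degrees) or a precomputed transform list
#'   from [forward_kinematics()].
#' @return Path length (m).
#' @export
path_length <- function(muscle, model, pose = list()) {
  if (is.character(muscle)) {
    muscle <- model$muscles[[muscle]] %||%
      stop("unknown muscle '", muscle, "'")
  }
  tf <- if (is.list(pose) && length(pose) > 0L &&
            is.matrix(pose[[1L]])) pose
        else forward_kinematics(model, pose)
  pts <- as.matrix(muscle$points[, c("x", "y", "z")])
  for (i in seq_len(nrow(pts)))
    pts[i, ] <- apply_transform(tf[[muscle$points$segment[i]]], pts[i, ])
  wraps <- lapply(muscle$wraps, function(w) {
    Tw <- tf[[w$segment]]
    w$origin <- as.numeric(apply_transform(Tw, w$origin))
    w$axis <- as.numeric(Tw[1:3, 1:3] %*% w$axis)
    w
  })
  total <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    total <- total + span_length(pts[i, ], pts[i + 1L, ], wraps)
  }
  total
}

span_length <- function(p, q, wraps) {
  for (w in wraps) {
    res <- wrap_span(p, q, w)
    if (!is.null(res)) return(res)
  }
  sqrt(sum((q - p)^2))
}

# Wrapped length over one surface, or NULL if the straight span clears it.
wrap_span <- function(p, q, w) {
  if (w$kind == "cylinder") {
    basis <- complete_basis(w$axis)
    P <- as.numeric((p - w$origin) %*% basis)
    Q <- as.numeric((q - w$origin) %*% basis)
    zp <- sum((p - w$origin) * w$axis)
    zq <- sum((q - w$origin) * w$axis)
  } else {
    # geodesic plane through p, q and the center
    P3 <- p - w$origin
    Q3 <- q - w$origin
    nrm <- cross3(P3, Q3)
    if (sqrt(sum(nrm^2)) < 1e-15 * max(1, sqrt(sum(P3^2)))) {
      # center collinear with the span: penetrates iff it crosses the ball
      if (point_segment_distance(w$origin, p, q) < w$radius)
        stop("muscle span passes through the center of wrap surface")
      return(NULL)
    }
    basis <- complete_basis(nrm / sqrt(sum(nrm^2)))
    P <- as.numeric(P3 %*% basis)
    Q <- as.numeric(Q3 %*% basis)
    zp <- 0; zq <- 0
  }
  d1 <- sqrt(sum(P^2)); d2 <- sqrt(sum(Q^2))
  R <- w$radius
  if (d1 < R * (1 - 1e-12) || d2 < R * (1 - 1e-12))
    stop("muscle path point lies strictly inside a wrap surface")
  gamma <- acos(max(-1, min(1, sum(P * Q) / (d1 * d2))))
  if (w$side == "long") {
    # active-arc flag: the path is constrained around the far side and
    # stays wrapped whether or not the chord penetrates
    gamma <- 2 * pi - gamma
  } else {
    # engagement: straight 2D span strictly penetrates the circle
    if (point_segment_distance(c(0, 0), P, Q) >= R) return(NULL)
  }
  phi <- gamma - acos(min(1, R / d1)) - acos(min(1, R / d2))
  if (phi <= 0) return(NULL)   # tangent configuration: not wrapped
  S <- sqrt(max(0, d1^2 - R^2)) + sqrt(max(0, d2^2 - R^2)) + R * phi
  sqrt(S^2 + (zq - zp)^2)
}

point_segment_distance <- function(x, a, b) {
  ab <- b - a
  t <- sum((x - a) * ab) / sum(ab^2)
  t <- max(0, min(1, t))
  sqrt(sum((a + t * ab - x)^2))
}

#' Signed muscle moment arm by tendon excursion
#'
#' The moment arm about one joint DOF is the negative derivative of
#' muscle-tendon length with respect to that joint angle (in radians),
#' evaluated by central finite difference. Positive values generate a
#' moment increasing the DOF's angle: about z, positive = extensor,
#' negative = flexor. ROM limits are deliberately not enforced, so sweeps
#' may pass beyond them for curve continuity.
#'
#' @param model a [body_model()].
#' @param muscle muscle name or [muscle_path()]; must cross the joint
#'   (points on both the child-side and parent-side of it).
#' @param joint joint name.
#' @param dof `"x"`, `"y"` or `"z"`.
#' @param pose base pose (degrees), default reference.
#' @param h_deg finite-difference half-step in degrees (default 0.25).
#' @return Moment arm (m).
#' @export
moment_arm <- function(model, muscle, joint, dof, pose = list(),
                       h_deg = 0.25) {
  mus <- if (is.character(muscle)) model$muscles[[muscle]] else muscle
  if (is.null(mus)) stop("unknown muscle")
  check_crosses(model, mus, joint)
  j <- model$joints[[joint]]
  if (!j$dof[[dof]]) stop("DOF '", dof, "' is locked at joint '", joint, "'")
  L <- function(delta) {
    p <- perturb_pose(pose, joint, dof, delta)
    path_length(mus, model, p)
  }
  -(L(h_deg) - L(-h_deg)) / (2 * deg2rad(h_deg))
}

perturb_pose <- function(pose, joint, dof, delta_deg) {
  ang <- pose[[joint]] %||% c(x = 0, y = 0, z = 0)
  if (is.null(names(ang))) names(ang) <- c("x", "y", "z")[seq_along(ang)]
  full <- c(x = 0, y = 0, z = 0)
  full[names(ang)] <- ang
  full[[dof]] <- full[[dof]] + delta_deg
  pose[[joint]] <- full
  pose
}

check_crosses <- function(model, mus, joint) {
  j <- model$joints[[joint]]
  if (is.null(j)) stop("unknown joint '", joint, "'")
  desc <- j$child
  repeat {
    more <- vapply(model$joints, function(x) x$parent %in% desc &&
                     !(x$child %in% desc), TRUE)
    if (!any(more)) break
    desc <- c(desc, vapply(model$joints[more], function(x) x$child, ""))
  }
  segs <- mus$points$segment
  if (!(any(segs %in% desc) && any(!segs %in% desc)))
    stop("muscle '", mus$acronym, "' does not cross joint '", joint, "'")
  invisible(desc)
}

#' Sweep a moment arm across a joint-angle grid
#'
#' Evaluates [moment_arm()] at each grid angle with all other DOFs held at
#' a base pose (reference pose by default, matching one-DOF-at-a-time
#' published sweeps).
#'
#' @inheritParams moment_arm
#' @param grid_deg strictly increasing angle grid (degrees).
#' @param base_pose pose holding the other DOFs.
#' @return Object of class `"moment_arm_curve"`: data frame `angle_deg`,
#'   `moment_arm_m` plus attributes `muscle`, `joint`, `dof`, `h_deg`.
#' @export
mma_sweep <- function(model, muscle, joint, dof, grid_deg, h_deg = 0.25,
                      base_pose = list()) {
  if (any(diff(grid_deg) <= 0)) stop("angle grid must be strictly increasing")
  r <- vapply(grid_deg, function(a)
    moment_arm(model, muscle, joint, dof,
               pose = perturb_pose(base_pose, joint, dof, a),
               h_deg = h_deg), 0)
  mus_name <- if (is.character(muscle)) muscle else muscle$acronym
  structure(data.frame(angle_deg = grid_deg, moment_arm_m = r),
            muscle = mus_name, joint = joint, dof = dof, h_deg = h_deg,
            class = c("moment_arm_curve", "data.frame"))
}

#' @export
print.moment_arm_curve <- function(x, ...) {
  cat(sprintf("moment arm curve: %s about %s/%s, %d angles, h = %g deg\n",
              attr(x, "muscle"), attr(x, "joint"), attr(x, "dof"),
              nrow(x), attr(x, "h_deg")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
plot.moment_arm_curve <- function(x, ...) {
  plot(x$angle_deg, x$moment_arm_m, type = "l",
       xlab = sprintf("%s %s angle (deg)", attr(x, "joint"), attr(x, "dof")),
       ylab = "moment arm (m)",
       main = attr(x, "muscle"), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Classify a muscle's action from its moment-arm curve
#'
#' Sign-based classification with a dead band: consistently positive
#' moment arms give the positive action for the DOF (extensor about z,
#' abductor about y, external rotator about x), consistently negative the
#' antagonist, values within the dead band everywhere "negligible", and
#' mixed signs "switching" with the zero-crossing angle interpolated
#' linearly between grid points.
#'
#' @param curve a `"moment_arm_curve"`.
#' @param tol dead band half-width (m), default 1e-4.
#' @return List: `action` (label), `theta_star_deg` (first zero crossing,
#'   `NA` unless switching).
#' @export
classify_action <- function(curve, tol = 1e-4) {
  r <- curve$moment_arm_m
  labels <- switch(attr(curve, "dof"),
                   z = c("extensor", "flexor"),
                   y = c("abductor", "adductor"),
                   x = c("external rotator", "internal rotator"))
  pos <- r > tol
  neg <- r < -tol
  if (!any(pos) && !any(neg))
    return(list(action = "negligible", theta_star_deg = NA_real_))
  if (any(pos) && any(neg)) {
    k <- which(r[-1L] * r[-length(r)] <= 0)[1L]
    th <- if (r[k] == r[k + 1L]) curve$angle_deg[k]
          else curve$angle_deg[k] - r[k] *
            (curve$angle_deg[k + 1L] - curve$angle_deg[k]) /
            (r[k + 1L] - r[k])
    return(list(action = sprintf("switching(%s/%s)", labels[1L], labels[2L]),
                theta_star_deg = th))
  }
  list(action = if (any(pos)) labels[1L] else labels[2L],
       theta_star_deg = NA_real_)
}

#' Write moment-arm sweeps as tidy CSV
#'
#' One row per (muscle, joint, dof, angle); units declared in the header
#' comment line.
#'
#' @param curves a `"moment_arm_curve"` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mma_csv <- function(curves, path) {
  if (inherits(curves, "moment_arm_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, function(cv)
    data.frame(muscle = attr(cv, "muscle"), joint = attr(cv, "joint"),
               dof = attr(cv, "dof"), angle_deg = cv$angle_deg,
               moment_arm_m = cv$moment_arm_m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# angles in degrees, moment arms in meters", con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
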