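#' Assemble a body model
#'
#' The central container: segments (with optional meshes, densities and
#' mass properties), joints (JCS placement in the global reference pose,
#' DOF flags, ROM limits, cartilage offsets, articular patches), muscles,
#' anatomical landmarks (acetabular/glenoid midpoints, foot support extent),
#' limb chains and preset poses. All geometry is stored in the reference
#' pose in the global anatomical frame (+X craniad, +Y left, +Z dorsad);
#' poses are applied by [forward_kinematics()].
#'
#' @param segments named list; each element may carry `mesh` ([trimesh()]),
#'   `density` (kg/m^3), `shape` ([segment_shape()]) and/or `mass_props`.
#' @param joints named list of [joint_def()] entries.
#' @param muscles named list of [muscle_path()] objects.
#' @param landmarks named list of `list(point =, segment =)`.
#' @param chains named list, each `list(joints = <character>,
#'   end_landmark = <name or NULL>)` declaring limb chains proximal to
#'   distal.
#' @param poses named list of preset poses.
#' @return Object of class `"body_model"`.
#' @export
body_model <- function(segments, joints = list(), muscles = list(),
                       landmarks = list(), chains = list(), poses = list()) {
  if (is.null(names(segments)) || any(!nzchar(names(segments))))
    stop("segments must be a named list")
  for (jn in names(joints)) {
    j <- joints[[jn]]
    for (side in c("parent", "child"))
      if (!j[[side]] %in% names(segments))
        stop("joint '", jn, "' references unknown segment '", j[[side]], "'")
  }
  for (mn in names(muscles)) {
    segs <- muscles[[mn]]$points$segment
    bad <- setdiff(unique(segs), names(segments))
    if (length(bad) > 0L)
      stop("muscle '", mn, "' bound to unknown segment(s): ",
           paste(bad, collapse = ", "))
  }
  for (ln in names(landmarks))
    if (!landmarks[[ln]]$segment %in% names(segments))
      stop("landmark '", ln, "' bound to unknown segment")
  structure(list(segments = segments, joints = joints, muscles = muscles,
                 landmarks = landmarks, chains = chains, poses = poses),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("body model: %d segments, %d joints, %d muscles\n",
              length(x$segments), length(x$joints), length(x$muscles)))
  for (jn in names(x$joints)) {
    j <- x$joints[[jn]]
    cat(sprintf("  %s: %s -> %s, DOF {%s}\n", jn, j$parent, j$child,
                paste(names(j$dof)[j$dof], collapse = ",")))
  }
  invisible(x)
}

#' Define a joint
#'
#' A joint shares one coordinate frame (the JCS) between a parent and child
#' segment at the reference pose. Rotations are applied in x, y, z order
#' about the JCS axes; positive z is extension, positive y abduction,
#' positive x external long-axis rotation. Joints allow rotations only, no
#' translations. Hips and shoulders carry three DOFs, all other limb joints
#' a single flexion-extension DOF.
#'
#' @param name joint name.
#' @param parent,child segment names.
#' @param origin JCS origin in the global reference pose (m).
#' @param axes 3 x 3 right-handed orthonormal JCS axes (columns x, y, z).
#' @param dof character vector naming free rotations, subset of
#'   `c("x", "y", "z")`.
#' @param rom named list of per-DOF `c(min_deg, max_deg)` limits (inclusive;
#'   `min <= 0 <= max` so the reference pose is always admissible).
#' @param cartilage_offset translation (m) added to the JCS origin at model
#'   build to make room for articular cartilage (zero at hip and ankle,
#'   which articulate tightly).
#' @param articular_patch optional `list(parent =, child =)` vertex-index
#'   vectors marking the articular surfaces on each segment mesh (excluded
#'   from collision tests, used for the disarticulation criterion).
#' @return A joint definition list.
#' @export
joint_def <- function(name, parent, child, origin, axes = diag(3),
                      dof = "z", rom = list(),
                      cartilage_offset = c(0, 0, 0),
                      articular_patch = NULL) {
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  dimnames(axes) <- NULL
  if (max(abs(t(axes) %*% axes - diag(3))) > 1e-8 || det(axes) < 0)
    stop("JCS axes must be right-handed orthonormal")
  dof_flags <- c(x = FALSE, y = FALSE, z = FALSE)
  dof_flags[match.arg(dof, c("x", "y", "z"), several.ok = TRUE)] <- TRUE
  if (length(rom) == 0L) rom <- list()
  for (ax in names(rom)) {
    lim <- rom[[ax]]
    if (!ax %in% c("x", "y", "z") || length(lim) != 2L)
      stop("rom entries must be named x/y/z with c(min, max)")
    if (lim[1L] > 0 || lim[2L] < 0)
      stop("ROM must bracket 0 deg (reference pose admissible): ", name,
           " ", ax)
  }
  list(name = name, parent = parent, child = child,
       origin = as.numeric(origin) + as.numeric(cartilage_offset),
       axes = axes, dof = dof_flags, rom = rom,
       cartilage_offset = as.numeric(cartilage_offset),
       articular_patch = articular_patch)
}

# Root segments: those never appearing as a child.
model_roots <- function(model) {
  children <- vapply(model$joints, function(j) j$child, "")
  setdiff(names(model$segments), children)
}

validate_pose <- function(model, pose) {
  if (is.null(pose)) pose <- list()
  for (jn in names(pose)) {
    if (!jn %in% names(model$joints))
      stop("pose names unknown joint '", jn, "'")
    ang <- pose[[jn]]
    if (is.null(names(ang)))
      names(ang) <- c("x", "y", "z")[seq_along(ang)]
    full <- c(x = 0, y = 0, z = 0)
    full[names(ang)] <- ang
    flags <- model$joints[[jn]]$dof
    off <- names(full)[!flags & abs(full) > 1e-12]
    if (length(off) > 0L)
      stop("pose sets locked DOF(s) ", paste(off, collapse = ","),
           " of joint '", jn, "'")
    pose[[jn]] <- full
  }
  pose
}

#' Forward kinematics: pose the skeleton by joint angles
#'
#' Computes, for every segment, the rigid transform mapping its reference
#' placement to the posed placement. Each joint contributes
#' `P Rx(ax) Ry(ay) Rz(az) P^-1` composed onto its parent's transform,
#' where `P` places the JCS in the global reference pose. The all-zero pose
#' therefore reproduces the reference placements exactly.
#'
#' @param model a [body_model()].
#' @param pose named list, joint name -> named angles in degrees
#'   (e.g. `list(hip = c(x = 10, y = 20, z = 30), knee = c(z = -30))`).
#'   Angles on locked DOFs are an error.
#' @return Named list of 4 x 4 transforms, one per segment.
#' @export
forward_kinematics <- function(model, pose = list()) {
  pose <- validate_pose(model, pose)
  transforms <- stats::setNames(
    rep(list(diag(4)), length(model$segments)), names(model$segments))
  # breadth-first from the roots
  pending <- model$joints
  placed <- model_roots(model)
  while (length(pending) > 0L) {
    ready <- vapply(pending, function(j) j$parent %in% placed, TRUE)
    if (!any(ready))
      stop("joint graph is not a tree rooted at a free segment")
    for (j in pending[ready]) {
      ang <- pose[[j$name]] %||% c(x = 0, y = 0, z = 0)
      P <- rigid_transform(j$axes, j$origin)
      R <- rigid_transform(euler_xyz(ang[c("x", "y", "z")]))
      transforms[[j$child]] <-
        transforms[[j$parent]] %*% P %*% R %*% solve(P)
      placed <- c(placed, j$child)
    }
    pending <- pending[!ready]
  }
  transforms
}

#' Check a pose against declared ROM limits
#'
#' Limits are inclusive: an angle exactly at a limit is legal. Joints or
#' DOFs without declared limits are never violated.
#'
#' @param pose named pose list (degrees), as for [forward_kinematics()].
#' @param model a [body_model()].
#' @return Data frame of violations with columns `joint`, `dof`, `angle`
#'   and `limit`; zero rows iff the pose is admissible.
#' @export
rom_check <- function(pose, model) {
  pose <- validate_pose(model, pose)
  out <- data.frame(joint = character(0), dof = character(0),
                    angle = numeric(0), limit = numeric(0))
  for (jn in names(pose)) {
    rom <- model$joints[[jn]]$rom
    for (ax in names(rom)) {
      a <- pose[[jn]][[ax]]
      lim <- rom[[ax]]
      if (a < lim[1L])
        out <- rbind(out, data.frame(joint = jn, dof = ax, angle = a,
                                     limit = lim[1L]))
      else if (a > lim[2L])
        out <- rbind(out, data.frame(joint = jn, dof = ax, angle = a,
                                     limit = lim[2L]))
    }
  }
  out
}

#' Scan one joint DOF for its motion range
#'
#' Automated proxy for the manual judgment used to set ROM limits: the DOF
#' is swept in both directions from 0 deg on a fixed grid, and the scan in
#' each direction stops at the last angle before either (a) any
#' triangle-triangle intersection between the parent and child segment
#' meshes, excluding faces touching the declared articular patches, or (b)
#' the articular-surface centroid separation exceeding the disarticulation
#' gap threshold. Results on real bone meshes are not expected to match
#' judgment-based published limits; those ship as a fixture instead.
#'
#' @param model a [body_model()] whose parent and child segments carry
#'   meshes.
#' @param joint joint name.
#' @param dof `"x"`, `"y"` or `"z"` (must be a free DOF).
#' @param step_deg grid step (> 0), default 1.
#' @param gap_m disarticulation threshold (m), default 0.005; `Inf`
#'   disables the criterion. Requires a declared articular patch.
#' @param collision test bone-bone collision (default `TRUE`).
#' @param range_deg scan extent, default `c(-180, 180)`.
#' @return `c(min_deg, max_deg)`: the admissible interval found.
#' @export
rom_scan <- function(model, joint, dof, step_deg = 1, gap_m = 0.005,
                     collision = TRUE, range_deg = c(-180, 180)) {
  if (step_deg <= 0) stop("grid step must be > 0")
  j <- model$joints[[joint]]
  if (is.null(j)) stop("unknown joint '", joint, "'")
  if (!j$dof[[dof]]) stop("DOF '", dof, "' is locked at joint '", joint, "'")
  pm <- model$segments[[j$parent]]$mesh
  cm <- model$segments[[j$child]]$mesh
  if (collision && (is.null(pm) || is.null(cm)))
    stop("collision scan needs meshes on both '", j$parent, "' and '",
         j$child, "'")
  patch <- j$articular_patch

  admissible <- function(angle) {
    pose <- stats::setNames(list(stats::setNames(
      replace(c(0, 0, 0), match(dof, c("x", "y", "z")), angle),
      c("x", "y", "z"))), joint)
    tf <- forward_kinematics(model, pose)
    Tp <- tf[[j$parent]]; Tc <- tf[[j$child]]
    if (is.finite(gap_m)) {
      if (is.null(patch))
        stop("disarticulation criterion needs an articular_patch on '",
             joint, "'")
      cp <- colMeans(apply_transform(
        Tp, pm$vertices[patch$parent, , drop = FALSE]))
      cc <- colMeans(apply_transform(
        Tc, cm$vertices[patch$child, , drop = FALSE]))
      if (sqrt(sum((cp - cc)^2)) > gap_m) return(FALSE)
    }
    if (collision) {
      ex_p <- patch_faces(pm, patch$parent)
      ex_c <- patch_faces(cm, patch$child)
      if (meshes_intersect(transform_mesh(pm, Tp), transform_mesh(cm, Tc),
                           exclude_a = ex_p, exclude_b = ex_c))
        return(FALSE)
    }
    TRUE
  }

  if (!admissible(0))
    stop("reference pose (0 deg) already violates the scan criteria at '",
         joint, "'")
  scan_dir <- function(sign) {
    last <- 0
    k <- 1L
    repeat {
      a <- sign * k * step_deg
      if (a < range_deg[1L] || a > range_deg[2L]) return(last)
      if (!admissible(a)) return(last)
      last <- a
      k <- k + 1L
    }
  }
  c(scan_dir(-1), scan_dir(+1))
}

patch_faces <- function(mesh, patch_vertices) {
  if (is.null(patch_vertices)) return(integer(0))
  which(rowSums(matrix(mesh$faces %in% patch_vertices,
                       nrow(mesh$faces))) > 0L)
}
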