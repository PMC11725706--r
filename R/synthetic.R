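# Seeded generators for every input class the pipeline needs, with known
# ground truth recorded alongside, so all downstream stages are testable
# without scan data. All generators are pure functions of (seed, params):
# the caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic articulated skeleton with known answers
#'
#' Box-proxy bones for a pelvis-femur-crus-pes hindlimb chain (plus a
#' simple upperarm-forearm forelimb), with a 3-DOF hip and shoulder and
#' single-DOF hinge knee, ankle, MTP and elbow — the standard archosaur
#' DOF scheme. Hinge muscles are placed with attachments at recorded radii
#' from the joint center in the hinge plane, so each one's moment arm has
#' the law-of-cosines closed form r(q) = -a b sin(d0 + q) / L(q), recorded
#' in the ground-truth table. Default dimensions are scaled to the
#' published skeletal summary (femur 0.179 m, hindlimb 0.320 m, GA
#' 0.355 m) so outputs land in a realistic regime.
#'
#' @param seed integer seed; the same seed reproduces an identical bundle.
#' @param dims named list of segment lengths (m): `femur`, `crus`, `pes`,
#'   `toe`, `upperarm`, `forearm`, `ga`.
#' @param n_muscles number of hinge muscles to place across the knee,
#'   ankle and MTP joints (default 9).
#' @return Object of class `"synthetic_skeleton"`: `model`
#'   ([body_model()]), `truth` (true hinge axes, segment mass properties,
#'   per-muscle closed-form parameters), `seed`.
#' @export
make_skeleton <- function(seed, dims = list(), n_muscles = 9L) {
  d <- utils::modifyList(list(femur = 0.179, crus = 0.141, pes = 0.08,
                              toe = 0.04, upperarm = 0.12, forearm = 0.102,
                              ga = 0.355), dims)
  if (any(unlist(d) <= 0)) stop("all dimensions must be positive")
  if (n_muscles < 0) stop("n_muscles must be >= 0")
  with_seed(seed, make_skeleton_impl(d, n_muscles, seed))
}

make_skeleton_impl <- function(d, n_muscles, seed) {
  # limb hangs ventrad (-Z); flexion-extension axis is mediolateral (+Y),
  # mapped to the JCS z-axis; the proximodistal axis (-Z) is the JCS x-axis
  jcs_axes <- cbind(x = c(0, 0, -1), y = c(-1, 0, 0), z = c(0, 1, 0))
  hip_o <- c(0, 0, 0)
  knee_o <- c(0, 0, -d$femur)
  ankle_o <- c(0, 0, -d$femur - d$crus)
  mtp_o <- ankle_o + c(d$pes, 0, 0)       # plantigrade pes points craniad
  shoulder_o <- c(d$ga, 0, 0)
  elbow_o <- shoulder_o + c(0, 0, -d$upperarm)
  wrist_o <- elbow_o + c(0, 0, -d$forearm)

  box_volumes <- list()
  seg_box <- function(name, a, b, half_width, shrink = 0.15) {
    # box along the a -> b line, shrunk so adjacent bones leave joint gaps
    mid <- (a + b) / 2
    len <- sqrt(sum((b - a)^2)) * (1 - shrink)
    u <- (b - a) / sqrt(sum((b - a)^2))
    basis <- complete_basis(u)
    R <- cbind(basis[, 1L], basis[, 2L], u)
    box_volumes[[name]] <<- (2 * half_width)^2 * len
    m <- box_mesh(c(half_width * 2, half_width * 2, len))
    transform_mesh(m, rigid_transform(R, mid))
  }
  box_volumes$pelvis <- d$ga * 1.2 * 0.10 * 0.10
  segments <- list(
    pelvis = list(mesh = box_mesh(c(d$ga * 1.2, 0.10, 0.10),
                                  center = c(d$ga / 2, 0, 0.07)),
                  density = 1000),
    femur = list(mesh = seg_box("femur", hip_o, knee_o, 0.018),
                 density = 1000),
    crus = list(mesh = seg_box("crus", knee_o, ankle_o, 0.013),
                density = 1000),
    pes = list(mesh = seg_box("pes", ankle_o, mtp_o, 0.010),
               density = 1000),
    toe = list(mesh = seg_box("toe", mtp_o, mtp_o + c(d$toe, 0, 0), 0.006),
               density = 1000),
    upperarm = list(mesh = seg_box("upperarm", shoulder_o, elbow_o, 0.012),
                    density = 1000),
    forearm = list(mesh = seg_box("forearm", elbow_o, wrist_o, 0.009),
                   density = 1000))

  joints <- list(
    hip = joint_def("hip", "pelvis", "femur", hip_o, jcs_axes,
                    dof = c("x", "y", "z"),
                    rom = list(z = c(-65, 55), y = c(-10, 70),
                               x = c(-50, 50))),
    knee = joint_def("knee", "femur", "crus", knee_o, jcs_axes, dof = "z",
                     rom = list(z = c(-110, 0))),
    ankle = joint_def("ankle", "crus", "pes", ankle_o, jcs_axes, dof = "z",
                      rom = list(z = c(-50, 30))),
    mtp3 = joint_def("mtp3", "pes", "toe", mtp_o, jcs_axes, dof = "z",
                     rom = list(z = c(-80, 50))),
    shoulder = joint_def("shoulder", "pelvis", "upperarm", shoulder_o,
                         jcs_axes, dof = c("x", "y", "z")),
    elbow = joint_def("elbow", "upperarm", "forearm", elbow_o, jcs_axes,
                      dof = "z"))

  hinge_of <- c(knee = "knee", ankle = "ankle", mtp3 = "mtp3")
  hinge_origin <- list(knee = knee_o, ankle = ankle_o, mtp3 = mtp_o)
  hinge_parent <- c(knee = "femur", ankle = "crus", mtp3 = "pes")
  hinge_child <- c(knee = "crus", ankle = "pes", mtp3 = "toe")
  pool <- list(
    knee = c("IT1", "AMB", "FMTE", "FMTI", "FTE", "FTI1", "FTI3", "PIT"),
    ankle = c("GE", "GI", "FC", "TA", "EDL", "FL"),
    mtp3 = c("FDL", "FHL", "EDB", "FDB"))
  muscles <- list()
  truth_rows <- list()
  used <- c(knee = 0L, ankle = 0L, mtp3 = 0L)
  jn_cycle <- rep(names(hinge_of), length.out = n_muscles)
  for (k in seq_len(n_muscles)) {
    jn <- jn_cycle[k]
    used[jn] <- used[jn] + 1L
    nm <- pool[[jn]][(used[jn] - 1L) %% length(pool[[jn]]) + 1L]
    nm <- if (used[jn] > length(pool[[jn]]))
      paste0(nm, "_", used[jn]) else nm
    a <- stats::runif(1, 0.04, 0.10)       # parent attachment radius (m)
    b <- stats::runif(1, 0.04, 0.10)       # child attachment radius
    alpha <- stats::runif(1, 100, 170) * pi / 180   # parent ray, hinge plane
    beta <- stats::runif(1, -80, -10) * pi / 180    # child ray at 0 deg
    o <- hinge_origin[[jn]]
    pt_par <- o + a * c(cos(alpha), 0, sin(alpha))
    pt_chi <- o + b * c(cos(beta), 0, sin(beta))
    muscles[[nm]] <- muscle_path(nm, data.frame(
      x = c(pt_par[1L], pt_chi[1L]), y = c(pt_par[2L], pt_chi[2L]),
      z = c(pt_par[3L], pt_chi[3L]),
      segment = c(hinge_parent[[jn]], hinge_child[[jn]])))
    truth_rows[[nm]] <- data.frame(
      muscle = nm, joint = jn, a = a, b = b, delta0_rad = alpha - beta)
  }
  # two straight hip muscles following the pelvis -> femur topology
  muscles$IF <- muscle_path("IF", data.frame(
    x = c(-0.03, 0.01), y = c(0.03, 0.025), z = c(0.05, -0.05),
    segment = c("pelvis", "femur")))
  muscles$CFL <- muscle_path("CFL", data.frame(
    x = c(-0.12, -0.01), y = c(0.01, 0.01), z = c(0.02, -0.07),
    segment = c("pelvis", "femur")))

  landmarks <- list(
    acetabulum = list(point = hip_o, segment = "pelvis"),
    glenoid = list(point = shoulder_o, segment = "pelvis"),
    toe_tip = list(point = mtp_o + c(d$toe, 0, 0), segment = "toe"),
    wrist = list(point = wrist_o, segment = "forearm"))
  chains <- list(
    hindlimb = list(joints = c("hip", "knee", "ankle")),
    forelimb = list(joints = c("shoulder", "elbow"),
                    end_landmark = "wrist"))

  model <- body_model(segments, joints, muscles, landmarks, chains,
                      poses = list(
                        reference = list(),
                        realistic = list(hip = c(z = -10), knee = c(z = -10),
                                         ankle = c(z = -10),
                                         elbow = c(z = -10),
                                         shoulder = c(z = 10))))
  truth <- list(
    hinge_axes = list(knee = c(0, 1, 0), ankle = c(0, 1, 0),
                      mtp3 = c(0, 1, 0)),
    jcs_axes = jcs_axes,
    segment_volume_m3 = box_volumes,   # analytic box volumes
    segment_mass_kg = lapply(box_volumes, function(v) v * 1000),
    muscle_closed_form = if (length(truth_rows) > 0L)
      do.call(rbind, truth_rows) else NULL,
    dims = d)
  structure(list(model = model, truth = truth, seed = seed),
            class = "synthetic_skeleton")
}

#' @export
print.synthetic_skeleton <- function(x, ...) {
  cat("synthetic skeleton, seed", x$seed, "\n")
  print(x$model)
  invisible(x)
}

#' Closed-form moment arm for a generated hinge muscle
#'
#' Evaluates the recorded law-of-cosines ground truth of a
#' [make_skeleton()] muscle: with attachment radii a, b and included-angle
#' offset d0, L(q) = sqrt(a^2 + b^2 - 2 a b cos(d0 + q)) and
#' r(q) = -a b sin(d0 + q) / L(q).
#'
#' @param skeleton a `"synthetic_skeleton"`.
#' @param muscle muscle acronym present in the ground-truth table.
#' @param angle_deg joint angle(s), degrees.
#' @return Moment arm(s), m.
#' @export
hinge_truth_moment_arm <- function(skeleton, muscle, angle_deg) {
  tr <- skeleton$truth$muscle_closed_form
  row <- tr[tr$muscle == muscle, ]
  if (nrow(row) != 1L) stop("no closed form recorded for '", muscle, "'")
  th <- row$delta0_rad + deg2rad(angle_deg)
  L <- sqrt(row$a^2 + row$b^2 - 2 * row$a * row$b * cos(th))
  -row$a * row$b * sin(th) / L
}

#' Generate hoop-built body segments with analytic volumes
#'
#' Octagonal prisms and linear tapers (optionally with a concentric air
#' cavity) whose volumes are recorded: prisms exactly (shoelace area times
#' length), tapers by the conical-frustum formula
#' V = h/3 (A1 + A2 + sqrt(A1 A2)) which the triangulated loft matches to
#' well under half a percent.
#'
#' @param seed integer seed.
#' @param n_segments number of segments to generate.
#' @param stations_per_segment hoops per stack (>= 2).
#' @param taper if `TRUE` (default) alternate prisms and tapers.
#' @param cavity_fraction cross-sectional area fraction occupied by a
#'   concentric cavity (0 disables).
#' @return List of `list(shape = segment_shape, true_volume_m3,
#'   exact (logical), cavity_fraction)`.
#' @export
make_hoop_body <- function(seed, n_segments = 3L, stations_per_segment = 4L,
                           taper = TRUE, cavity_fraction = 0) {
  if (stations_per_segment < 2L) stop("need >= 2 stations per segment")
  if (cavity_fraction < 0 || cavity_fraction >= 1)
    stop("cavity_fraction must be in [0, 1)")
  with_seed(seed, {
    lapply(seq_len(n_segments), function(i) {
      r <- stats::runif(1, 0.03, 0.12)
      len <- stats::runif(1, 0.1, 0.4)
      s2 <- if (taper && i %% 2L == 0L) stats::runif(1, 0.4, 0.9) else 1
      st <- seq(0, len, length.out = stations_per_segment)
      scales <- 1 + (s2 - 1) * st / len
      outer <- lapply(seq_along(st), function(k)
        octagon_hoop(r * scales[k], st[k]))
      area <- octagon_area(r)
      true_v <- if (s2 == 1) {
        area * len
      } else {
        a1 <- area; a2 <- area * s2^2
        len / 3 * (a1 + a2 + sqrt(a1 * a2))
      }
      cav <- list()
      if (cavity_fraction > 0) {
        rc <- r * sqrt(cavity_fraction)
        cav <- list(lapply(seq_along(st), function(k)
          octagon_hoop(rc * scales[k], st[k])))
        true_v_cav <- true_v * cavity_fraction
      } else true_v_cav <- 0
      list(shape = segment_shape(paste0("seg", i), outer, cavities = cav,
                                 density = 1000, cavity_density = 0),
           true_volume_m3 = true_v, true_cavity_volume_m3 = true_v_cav,
           exact = (s2 == 1), cavity_fraction = cavity_fraction)
    })
  })
}

octagon_area <- function(circumradius) {
  2 * sqrt(2) * circumradius^2
}

#' Sample an articular-surface point patch from a known primitive
#'
#' Surface samples of a sphere, cylinder, plane or ellipsoid with optional
#' isotropic Gaussian noise, for exercising [fit_primitive()].
#'
#' @param primitive list with `kind` plus the parameters of that kind:
#'   sphere `center`, `radius`; cylinder `center`, `axis`, `radius` and
#'   optional `height` (default 2 radius); plane `center`, `normal` and
#'   optional `extent`; ellipsoid `center`, `radii`, optional `axes`.
#' @param n number of points (must meet the kind's minimum: sphere 4,
#'   plane 3, cylinder 6, ellipsoid 9).
#' @param sigma isotropic noise SD (m).
#' @param seed integer seed.
#' @return n x 3 point matrix.
#' @export
make_articular_patch <- function(primitive, n, sigma = 0, seed = 1) {
  kind <- primitive$kind
  minn <- c(sphere = 4L, plane = 3L, cylinder = 6L, ellipsoid = 9L)[[kind]]
  if (is.null(minn)) stop("unknown primitive kind '", kind, "'")
  if (n < minn) stop(kind, " patch needs >= ", minn, " points")
  with_seed(seed, {
    pts <- switch(kind,
      sphere = {
        u <- matrix(stats::rnorm(3 * n), n)
        u <- u / sqrt(rowSums(u^2))
        sweep(u * primitive$radius, 2L, primitive$center, `+`)
      },
      plane = {
        ext <- primitive$extent %||% 1
        basis <- complete_basis(primitive$normal)
        q <- matrix(stats::runif(2 * n, -ext, ext), n)
        sweep(q %*% t(basis), 2L, primitive$center, `+`)
      },
      cylinder = {
        h <- primitive$height %||% (2 * primitive$radius)
        axis <- primitive$axis / sqrt(sum(primitive$axis^2))
        basis <- complete_basis(axis)
        th <- stats::runif(n, 0, 2 * pi)
        zz <- stats::runif(n, -h / 2, h / 2)
        q <- primitive$radius * cbind(cos(th), sin(th))
        sweep(q %*% t(basis) + outer(zz, axis), 2L, primitive$center, `+`)
      },
      ellipsoid = {
        axes <- primitive$axes %||% diag(3)
        u <- matrix(stats::rnorm(3 * n), n)
        u <- u / sqrt(rowSums(u^2))
        sweep(t(axes %*% t(u * rep(primitive$radii, each = n))),
              2L, primitive$center, `+`)
      })
    pts + matrix(stats::rnorm(3 * n, 0, sigma), n)
  })
}

#' Generate two-class Gaussian posture feature records
#'
#' Labeled samples emulating the structure of the bipedal/quadrupedal
#' training data: class-conditional Gaussians in the discriminant feature
#' space (log10 body mass, dimensionless COM, forelimb/hindlimb ratio),
#' back-transformed into feature records.
#'
#' @param n_per_class samples per class (length 1 or 2).
#' @param means 2 x p matrix of class means in feature space (row 1 =
#'   quadrupedal, row 2 = bipedal); defaults emulate a heavier,
#'   front-loaded quadruped class versus a lighter bipedal class.
#' @param cov shared p x p covariance (must be symmetric positive
#'   definite).
#' @param seed integer seed.
#' @param labels class labels, default `c("quadrupedal", "bipedal")`.
#' @return For the default 3 features: a record data frame with columns
#'   `taxon`, `mass_kg`, `com_per_ga`, `forelimb_m`, `hindlimb_m`,
#'   `posture`. Otherwise `list(x, labels)`.
#' @export
make_posture_features <- function(n_per_class = 25L,
                                  means = rbind(c(1.5, 0.35, 0.90),
                                                c(1.2, 0.25, 0.55)),
                                  cov = diag(c(0.04, 0.004, 0.01)),
                                  seed = 1,
                                  labels = c("quadrupedal", "bipedal")) {
  means <- as.matrix(means)
  p <- ncol(means)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) ||
      any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("cov must be symmetric positive definite")
  n_per_class <- rep_len(as.integer(n_per_class), 2L)
  with_seed(seed, {
    x <- rbind(MASS::mvrnorm(n_per_class[1L], means[1L, ], cov),
               MASS::mvrnorm(n_per_class[2L], means[2L, ], cov))
    g <- factor(rep(labels, n_per_class), levels = labels)
    if (p != 3L) return(list(x = x, labels = g))
    hind <- 0.32
    data.frame(taxon = sprintf("synth_%03d", seq_len(nrow(x))),
               mass_kg = 10^x[, 1L], com_per_ga = x[, 2L],
               forelimb_m = x[, 3L] * hind, hindlimb_m = hind,
               posture = g)
  })
}
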