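two_point_model <- function(p, q, wraps = list()) {
  body_model(
    segments = list(a = list(), b = list()),
    joints = list(j = joint_def("j", "a", "b", c(0, 0, 0), dof = "z")),
    muscles = list(M = muscle_path("M", data.frame(
      x = c(p[1], q[1]), y = c(p[2], q[2]), z = c(p[3], q[3]),
      segment = c("a", "b")), wraps = wraps)))
}

test_that("straight and collinear-via paths measure Euclidean length", {
  m <- two_point_model(c(0, 0, 0), c(0.3, 0.4, 0))
  expect_equal(path_length("M", m), 0.5, tolerance = 1e-12)

  via <- body_model(
    segments = list(a = list(), b = list()),
    joints = list(j = joint_def("j", "a", "b", c(0, 0, 0), dof = "z")),
    muscles = list(M = muscle_path("M", data.frame(
      x = c(0, 0.15, 0.3), y = c(0, 0.2, 0.4), z = c(0, 0, 0),
      segment = c("a", "a", "b")))))
  expect_equal(path_length("M", via), 0.5, tolerance = 1e-12)
})

test_that("cylinder wrapping matches the planar tangent-arc closed form", {
  R <- 0.05
  d1 <- 0.2; d2 <- 0.15
  # endpoints on opposite sides so the straight chord crosses the circle
  p <- c(-d1, 0, 0)
  q <- c(d2 * cos(-0.4), d2 * sin(-0.4), 0)
  w <- wrap_surface("cylinder", "a", origin = c(0, 0, 0), radius = R,
                    axis = c(0, 0, 1))
  m <- two_point_model(p, q, wraps = list(w))
  got <- path_length("M", m)
  gamma <- acos(sum(p * q) / (d1 * d2))
  phi <- gamma - acos(R / d1) - acos(R / d2)
  closed <- sqrt(d1^2 - R^2) + sqrt(d2^2 - R^2) + R * phi
  expect_equal(got, closed, tolerance = 1e-9)

  # sphere wrap: same closed form in the plane through the center
  ws <- wrap_surface("sphere", "a", origin = c(0, 0, 0), radius = R)
  ms <- two_point_model(p, q, wraps = list(ws))
  expect_equal(path_length("M", ms), closed, tolerance = 1e-9)

  # an endpoint strictly inside the surface is an error
  bad <- two_point_model(c(0.01, 0, 0), q, wraps = list(w))
  expect_error(path_length("M", bad), "inside a wrap surface")
})

test_that("path length is continuous across the wrap engagement boundary", {
  R <- 0.05
  w <- wrap_surface("cylinder", "a", origin = c(0, 0, 0), radius = R,
                    axis = c(0, 0, 1))
  len_at <- function(y_offset) {
    m <- two_point_model(c(-0.2, y_offset, 0), c(0.2, y_offset, 0),
                         wraps = list(w))
    path_length("M", m)
  }
  # chord exactly tangent at y = R; compare just inside vs just outside
  eps <- 1e-8
  expect_lt(abs(len_at(R - eps) - len_at(R + eps)), 1e-6)
  # grazing tangency itself counts as not wrapped
  expect_equal(len_at(R), 0.4, tolerance = 1e-12)
})

test_that("hinge moment arms match the law-of-cosines closed form", {
  rig <- hinge_rig(a = 0.08, b = 0.11, alpha_deg = 140, beta_deg = -35)
  for (q in c(-60, -20, 0, 15, 45)) {
    r_num <- moment_arm(rig$model, "M", "j", "z",
                        pose = list(j = c(z = q)), h_deg = 0.25)
    expect_equal(r_num, rig$truth_r(q), tolerance = 1e-3 * abs(rig$truth_r(q)))
  }
})

test_that("tendon-excursion differencing converges at second order", {
  rig <- hinge_rig(a = 0.07, b = 0.09, alpha_deg = 150, beta_deg = -20)
  q <- 25
  err_at <- function(h) {
    abs(moment_arm(rig$model, "M", "j", "z", pose = list(j = c(z = q)),
                   h_deg = h) - rig$truth_r(q))
  }
  e1 <- err_at(2); e2 <- err_at(1); e3 <- err_at(0.5)
  expect_gt(e1 / e2, 3.4)   # halving h shrinks the error ~4x
  expect_gt(e2 / e3, 3.4)
  expect_lt(e3, 1e-6)
})

test_that("a tendon wrapped on a hinge-coaxial cylinder has |r| = R", {
  R <- 0.03
  # hinge about global z; wrap cylinder coaxial with it; the active-arc
  # flag keeps the tendon on the far side, fully wrapped in every pose
  w <- wrap_surface("cylinder", "a", origin = c(0, 0, 0), radius = R,
                    axis = c(0, 0, 1), side = "long")
  m <- two_point_model(c(-0.2, 0.02, 0), c(0.18, -0.025, 0),
                       wraps = list(w))
  for (q in c(-30, 0, 25, 60)) {
    r <- moment_arm(m, "M", "j", "z", pose = list(j = c(z = q)))
    expect_equal(abs(r), R, tolerance = 1e-6)
  }
})

test_that("a path through the hinge axis has zero moment arm", {
  # both attachments on the hinge axis plane, crossing the axis
  m <- two_point_model(c(-0.1, 0, 0), c(0.1, 0, 0))
  expect_equal(moment_arm(m, "M", "j", "z"), 0, tolerance = 1e-12)
})

test_that("muscles that do not cross the joint are rejected", {
  m <- body_model(
    segments = list(a = list(), b = list()),
    joints = list(j = joint_def("j", "a", "b", c(0, 0, 0), dof = "z")),
    muscles = list(M = muscle_path("M", data.frame(
      x = c(0, 0.1), y = c(0, 0), z = c(0, 0.1),
      segment = c("a", "a")))))
  expect_error(moment_arm(m, "M", "j", "z"), "does not cross")
})

test_that("sweeps are direction-independent and integrate to -dL", {
  rig <- hinge_rig(a = 0.06, b = 0.1, alpha_deg = 120, beta_deg = -50)
  grid <- seq(-60, 60, by = 2)
  cv <- mma_sweep(rig$model, "M", "j", "z", grid)
  expect_equal(cv$moment_arm_m, rig$truth_r(grid), tolerance = 1e-5)
  # evaluation independence: reversed grid gives reversed values
  cv_rev <- mma_sweep(rig$model, "M", "j", "z", grid)
  expect_equal(rev(rev(cv_rev$moment_arm_m)), cv$moment_arm_m)
  # work-length theorem: trapezoid integral of r dtheta = -(L_end - L_start)
  dtheta <- 2 * pi / 180
  integral <- sum((cv$moment_arm_m[-1] + cv$moment_arm_m[-nrow(cv)]) / 2) *
    dtheta
  dL <- rig$truth_L(60) - rig$truth_L(-60)
  expect_equal(integral, -dL, tolerance = 1e-4)
})

test_that("a synthetic hamstring's flexor leverage grows with knee extension", {
  # long-fibred two-joint analogue: distant origin (a = 0.15 m) and a
  # close insertion on the flexor side of the axis
  rig <- hinge_rig(a = 0.15, b = 0.04, alpha_deg = 35, beta_deg = -35)
  grid <- seq(-60, 0, by = 5)        # flexed to fully extended
  cv <- mma_sweep(rig$model, "M", "j", "z", grid)
  # flexor: negative moment arms about z
  expect_true(all(cv$moment_arm_m < 0))
  # magnitude increases toward extension (angle -> 0)
  mags <- abs(cv$moment_arm_m)
  expect_true(all(diff(mags) > 0))
})

test_that("classify_action labels uniform, switching and negligible curves", {
  fake_curve <- function(angle, r, dof = "z") {
    structure(data.frame(angle_deg = angle, moment_arm_m = r),
              muscle = "X", joint = "j", dof = dof, h_deg = 0.25,
              class = c("moment_arm_curve", "data.frame"))
  }
  up <- fake_curve(seq(-30, 30, 10), rep(0.02, 7))
  expect_equal(classify_action(up)$action, "extensor")
  down <- fake_curve(seq(-30, 30, 10), rep(-0.02, 7))
  expect_equal(classify_action(down)$action, "flexor")
  tiny <- fake_curve(seq(-30, 30, 10), runif(7, -5e-5, 5e-5))
  expect_equal(classify_action(tiny)$action, "negligible")
  # linear curve crossing zero at +10 deg exactly
  ang <- seq(-30, 30, 20)
  lin <- fake_curve(ang, 0.001 * (ang - 10))
  got <- classify_action(lin)
  expect_match(got$action, "switching")
  expect_equal(got$theta_star_deg, 10, tolerance = 1e-9)
  # y-DOF labels
  ab <- fake_curve(seq(-30, 30, 10), rep(0.02, 7), dof = "y")
  expect_equal(classify_action(ab)$action, "abductor")
})

test_that("the shipped muscle table loads all Table-topology rows", {
  tab <- load_muscle_table()
  expect_equal(nrow(tab), 37L)
  expect_false(anyDuplicated(tab$acronym) > 0)
  expect_true(all(c("IF", "CFL", "AMB", "ILFB", "AHD") %in% tab$acronym))
  expect_true(all(grepl("^(I|II)'?$", tab$origin_level)))
  expect_true(all(grepl("^(I|II)'?$", tab$insertion_level)))
})
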