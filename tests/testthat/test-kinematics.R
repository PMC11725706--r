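test_that("zero pose reproduces reference placements exactly", {
  sk <- make_skeleton(1)
  tf <- forward_kinematics(sk$model, list())
  for (nm in names(tf)) expect_equal(tf[[nm]], diag(4))
})

test_that("a +90 deg hinge rotates the child about the JCS z-axis", {
  sk <- make_skeleton(1)
  tf <- forward_kinematics(sk$model, list(knee = c(z = 90)))
  # JCS z is global +Y at the knee; closed-form rotation about +Y through
  # the knee center
  knee_o <- sk$model$joints$knee$origin
  Ry90 <- matrix(c(cos(pi/2), 0, -sin(pi/2),
                   0, 1, 0,
                   sin(pi/2), 0, cos(pi/2)), 3, 3)   # column-major Ry(+90)
  expected <- rigid_transform(diag(3), knee_o) %*%
    rigid_transform(Ry90) %*% rigid_transform(diag(3), -knee_o)
  expect_equal(tf$crus, expected, tolerance = 1e-12)
  # parent segments unmoved
  expect_equal(tf$femur, diag(4))
})

test_that("3-DOF hip equals the explicit Rx Ry Rz matrix product", {
  sk <- make_skeleton(2)
  ang <- c(x = 10, y = 20, z = 30)
  tf <- forward_kinematics(sk$model, list(hip = ang))
  # independent oracle: build the product from scratch
  rx <- function(t) matrix(c(1,0,0, 0,cos(t),sin(t), 0,-sin(t),cos(t)), 3)
  ry <- function(t) matrix(c(cos(t),0,-sin(t), 0,1,0, sin(t),0,cos(t)), 3)
  rz <- function(t) matrix(c(cos(t),sin(t),0, -sin(t),cos(t),0, 0,0,1), 3)
  d2r <- pi / 180
  R_local <- rx(10 * d2r) %*% ry(20 * d2r) %*% rz(30 * d2r)
  A <- sk$model$joints$hip$axes
  o <- sk$model$joints$hip$origin
  expected <- rigid_transform(A %*% R_local %*% t(A)) |>
    (\(m) rigid_transform(diag(3), o) %*% m %*%
       rigid_transform(diag(3), -o))()
  expect_equal(tf$femur, expected, tolerance = 1e-12)
  # and propagates down the chain
  expect_equal(tf$crus, expected, tolerance = 1e-12)
})

test_that("FK transforms are proper rigid motions for random poses", {
  sk <- make_skeleton(3)
  set.seed(99)
  for (i in 1:5) {
    pose <- list(hip = c(x = runif(1, -50, 50), y = runif(1, -10, 70),
                         z = runif(1, -65, 55)),
                 knee = c(z = runif(1, -110, 0)),
                 ankle = c(z = runif(1, -50, 30)))
    tf <- forward_kinematics(sk$model, pose)
    for (m in tf) {
      R <- m[1:3, 1:3]
      expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  }
})

test_that("angles on locked DOFs are rejected", {
  sk <- make_skeleton(1)
  expect_error(forward_kinematics(sk$model, list(knee = c(x = 5))),
               "locked DOF")
  expect_error(forward_kinematics(sk$model, list(nojoint = c(z = 5))),
               "unknown joint")
  # zero on a locked DOF is fine
  expect_silent(forward_kinematics(sk$model, list(knee = c(x = 0, z = -10))))
})

test_that("rom_check applies inclusive limits and ignores undeclared ones", {
  sk <- make_skeleton(1)
  v <- rom_check(list(hip = c(z = 60)), sk$model)
  expect_equal(nrow(v), 1L)
  expect_equal(v$limit, 55)
  expect_equal(nrow(rom_check(list(hip = c(z = 55)), sk$model)), 0L)
  expect_equal(nrow(rom_check(list(hip = c(z = -65)), sk$model)), 0L)
  # shoulder has no declared limits: never violated
  expect_equal(nrow(rom_check(list(shoulder = c(z = 170)), sk$model)), 0L)
})

# Hinged-rod-vs-block rig with analytic first-contact angles at
# +/-40.3 deg: each block's inner face is the plane through the hinge axis
# at that azimuth, the block is thick in the sweep direction but narrower
# than the rod radially, so the rod pierces its end faces for every angle
# past contact (never fully contained).
contact_rig <- function(contact_deg = 40.3) {
  rod <- box_mesh(c(0.2, 1e-3, 1e-3), center = c(0.2, 0, 0))
  jcs <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))  # hinge about global z
  slab_at <- function(az_deg, side) {
    th <- az_deg * pi / 180
    u <- c(cos(th), sin(th), 0)           # along the contact ray
    nrm <- c(-sin(th), cos(th), 0)        # +90 deg from the ray
    R <- cbind(u, nrm, c(0, 0, 1))
    transform_mesh(box_mesh(c(0.10, 0.30, 0.05)),
                   rigid_transform(R, 0.2 * u + side * 0.15 * nrm))
  }
  parent_mesh <- local({
    a <- slab_at(contact_deg, +1)
    b <- slab_at(-contact_deg, -1)
    trimesh(rbind(a$vertices, b$vertices),
            rbind(a$faces, b$faces + nrow(a$vertices)),
            validate = FALSE, normalize = FALSE)
  })
  body_model(
    segments = list(base = list(mesh = parent_mesh),
                    arm = list(mesh = rod)),
    joints = list(hinge = joint_def("hinge", "base", "arm", c(0, 0, 0),
                                    jcs, dof = "z")))
}

test_that("rom_scan finds the analytic contact angle of hinged boxes", {
  model <- contact_rig(40.3)
  lim <- rom_scan(model, "hinge", "z", step_deg = 1, gap_m = Inf)
  expect_equal(lim[2], 40)
  expect_equal(lim[1], -40)
})

test_that("rom_scan returns the full range when nothing can stop it", {
  model <- contact_rig(40.3)
  lim <- rom_scan(model, "hinge", "z", step_deg = 30, gap_m = Inf,
                  range_deg = c(-90, 90))
  # with a 30 deg grid the first collision is at 60; last admissible 30
  expect_equal(lim, c(-30, 30))
  # far-apart convex bodies: no collision anywhere
  free <- body_model(
    segments = list(base = list(mesh = box_mesh(c(0.1, 0.1, 0.1),
                                                center = c(5, 5, 5))),
                    arm = list(mesh = box_mesh(c(0.1, 0.1, 0.1),
                                               center = c(-5, -5, -5)))),
    joints = list(hinge = joint_def("hinge", "base", "arm", c(0, 0, 0),
                                    dof = "z")))
  lim <- rom_scan(free, "hinge", "z", step_deg = 45, gap_m = Inf)
  expect_equal(lim, c(-180, 180))
})

test_that("rom_scan disarticulation widens monotonically with the gap", {
  # two touching boxes with articular patches; rotating separates the
  # patch centroids progressively
  base <- box_mesh(c(0.1, 0.1, 0.1), center = c(-0.05, 0, 0))
  arm <- box_mesh(c(0.3, 0.02, 0.02), center = c(0.16, 0, 0))
  patch_base <- which(abs(base$vertices[, 1]) < 1e-9)   # face at x = 0
  patch_arm <- which(abs(arm$vertices[, 1] - 0.01) < 1e-9)
  model <- body_model(
    segments = list(base = list(mesh = base), arm = list(mesh = arm)),
    joints = list(hinge = joint_def(
      "hinge", "base", "arm", c(-0.02, 0, 0), dof = "z",
      articular_patch = list(parent = patch_base, child = patch_arm))))
  spans <- vapply(c(0.012, 0.015, 0.02), function(g) {
    lim <- rom_scan(model, "hinge", "z", step_deg = 2, gap_m = g,
                    collision = FALSE)
    diff(lim)
  }, 0)
  expect_true(all(diff(spans) >= 0))
  expect_gt(spans[3], spans[1])
})

test_that("rom_scan refuses an already-colliding reference pose", {
  clash <- body_model(
    segments = list(base = list(mesh = box_mesh(c(0.2, 0.2, 0.2))),
                    arm = list(mesh = box_mesh(c(0.2, 0.2, 0.2)))),
    joints = list(hinge = joint_def("hinge", "base", "arm", c(0, 0, 0),
                                    dof = "z")))
  expect_error(rom_scan(clash, "hinge", "z", gap_m = Inf),
               "reference pose")
})
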