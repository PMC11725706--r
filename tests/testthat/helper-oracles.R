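# Independent geometric oracles, deliberately different algorithms from the
# package's divergence-theorem integrals: column integration on a fixed
# planar grid (the "voxel oracle"), plus seeded shape generators.

# Volume and COM by ray casting: a grid of vertical columns over the xy
# bounding box; each column's crossings with the surface are paired into
# inside intervals and integrated exactly along z. Grid of n x n columns is
# accuracy-equivalent to an n^3 voxelization for these smooth shapes.
voxel_oracle <- function(mesh, n = 200) {
  v <- mesh$vertices
  f <- mesh$faces
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  pad <- 1e-9 + 0.001 * max(hi - lo)
  lo <- lo - pad; hi <- hi + pad
  dx <- (hi[1] - lo[1]) / n
  dy <- (hi[2] - lo[2]) / n
  # irrational offset keeps columns off mesh edges
  xs <- lo[1] + (seq_len(n) - 1 + 0.5 + 1e-4 * sqrt(2)) * dx
  ys <- lo[2] + (seq_len(n) - 1 + 0.5 + 1e-4 * sqrt(3)) * dy
  cell <- integer(0); zval <- numeric(0)
  for (t in seq_len(nrow(f))) {
    tri <- v[f[t, ], , drop = FALSE]
    nz <- (tri[2,1]-tri[1,1])*(tri[3,2]-tri[1,2]) -
          (tri[2,2]-tri[1,2])*(tri[3,1]-tri[1,1])
    if (abs(nz) < 1e-14) next   # vertical triangle: measure-zero columns
    ix <- which(xs >= min(tri[,1]) & xs <= max(tri[,1]))
    iy <- which(ys >= min(tri[,2]) & ys <= max(tri[,2]))
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(ix = ix, iy = iy)
    px <- xs[g$ix]; py <- ys[g$iy]
    d <- (tri[2,1]-tri[1,1])*(tri[3,2]-tri[1,2]) -
         (tri[3,1]-tri[1,1])*(tri[2,2]-tri[1,2])
    l1 <- ((tri[2,1]-px)*(tri[3,2]-py) - (tri[3,1]-px)*(tri[2,2]-py)) / d
    l2 <- ((tri[3,1]-px)*(tri[1,2]-py) - (tri[1,1]-px)*(tri[3,2]-py)) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(inside)) next
    z <- l1[inside]*tri[1,3] + l2[inside]*tri[2,3] + l3[inside]*tri[3,3]
    cell <- c(cell, (g$ix[inside] - 1L) * n + g$iy[inside])
    zval <- c(zval, z)
  }
  area <- dx * dy
  sp <- split(zval, cell)
  ids <- as.integer(names(sp))
  cx <- xs[(ids - 1L) %/% n + 1L]
  cy <- ys[(ids - 1L) %% n + 1L]
  lens <- numeric(length(sp))
  mz_col <- numeric(length(sp))
  for (i in seq_along(sp)) {
    z <- sort(sp[[i]])
    if (length(z) %% 2L != 0L) next   # edge-grazing column: drop
    k <- seq(1, length(z), by = 2)
    lens[i] <- sum(z[k + 1] - z[k])
    mz_col[i] <- sum((z[k + 1]^2 - z[k]^2) / 2)
  }
  vol <- sum(lens) * area
  list(volume = vol,
       com = c(sum(cx * lens), sum(cy * lens), sum(mz_col)) * area / vol)
}

# Star-shaped seeded blob: radially modulated icosphere; watertight by
# construction (topology unchanged, radius stays positive).
random_blob <- function(seed, subdivisions = 3, amplitude = 0.25) {
  set.seed(seed)
  a <- runif(6, -amplitude, amplitude)
  m <- icosphere(1, subdivisions)
  v <- m$vertices
  th <- acos(pmin(1, pmax(-1, v[, 3])))
  ph <- atan2(v[, 2], v[, 1])
  r <- 1 + a[1]*sin(2*th)*cos(ph) + a[2]*cos(3*th) +
       a[3]*sin(th)*sin(2*ph) + a[4]*cos(2*th)*cos(2*ph) +
       a[5]*sin(3*th)*sin(ph) + a[6]*cos(th)
  m$vertices <- v * r
  m
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Hinged two-point muscle test rig: a hinge about +Y at the origin with
# attachments at radii a (parent) and b (child) in the xz plane; the
# closed-form length and moment arm follow the law of cosines.
hinge_rig <- function(a, b, alpha_deg = 135, beta_deg = -45) {
  jcs <- cbind(c(0, 0, -1), c(-1, 0, 0), c(0, 1, 0))  # z = +Y hinge
  al <- alpha_deg * pi / 180
  be <- beta_deg * pi / 180
  pa <- a * c(cos(al), 0, sin(al))
  pb <- b * c(cos(be), 0, sin(be))
  model <- body_model(
    segments = list(parent = list(), child = list()),
    joints = list(j = joint_def("j", "parent", "child",
                                c(0, 0, 0), jcs, dof = "z")),
    muscles = list(M = muscle_path("M", data.frame(
      x = c(pa[1], pb[1]), y = c(pa[2], pb[2]), z = c(pa[3], pb[3]),
      segment = c("parent", "child")))))
  delta0 <- al - be
  truth_L <- function(q_deg) {
    th <- delta0 + q_deg * pi / 180
    sqrt(a^2 + b^2 - 2 * a * b * cos(th))
  }
  truth_r <- function(q_deg) {
    th <- delta0 + q_deg * pi / 180
    -a * b * sin(th) / truth_L(q_deg)
  }
  list(model = model, truth_L = truth_L, truth_r = truth_r)
}
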