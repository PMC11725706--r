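shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

test_that("extruded octagon prisms reproduce shoelace area times length", {
  for (r in c(0.05, 0.31)) {
    h <- 0.8
    hoops <- lapply(seq(0, h, length.out = 5),
                    function(z) octagon_hoop(r, z, rotation_deg = 12))
    m <- loft_hoops(hoops)
    a <- shoelace_area(hoops[[1]]$vertices[, 1:2])
    expect_equal(mesh_volume(m), a * h, tolerance = 1e-12)
  }
  # irregular (but identical) octagons too
  set.seed(3)
  ang <- sort(runif(8, 0, 2 * pi))
  rad <- runif(8, 0.1, 0.3)
  poly <- cbind(rad * cos(ang), rad * sin(ang))
  hoops <- lapply(c(0, 0.2, 0.5), function(z)
    hoop(cbind(poly, z), station = z))
  expect_equal(mesh_volume(loft_hoops(hoops)),
               shoelace_area(poly) * 0.5, tolerance = 1e-12)
})

test_that("tapered lofts agree with the column-integration oracle", {
  h1 <- octagon_hoop(0.2, 0)
  h2 <- octagon_hoop(0.09, 0.5)
  m <- loft_hoops(list(h1, h2))
  o <- voxel_oracle(m, 200)
  expect_lt(abs(o$volume - mesh_volume(m)) / mesh_volume(m), 0.005)
})

test_that("degenerate hoop inputs are rejected", {
  expect_error(loft_hoops(list(octagon_hoop(0.1, 0))), "at least 2")
  # bow-tie octagon: swap two vertices to force self-intersection
  v <- octagon_hoop(0.1, 0)$vertices
  v[c(1, 2), ] <- v[c(2, 1), ]
  expect_error(hoop(v, 0), "self-intersecting")
  expect_error(loft_hoops(list(octagon_hoop(0.1, 0.5),
                               octagon_hoop(0.1, 0.1))),
               "strictly increasing")
})

test_that("segment_mass reduces, cancels and subtracts cavities exactly", {
  outer <- lapply(c(0, 0.3, 0.6), function(z) octagon_hoop(0.2, z))
  inner <- lapply(c(0.001, 0.3, 0.599), function(z) octagon_hoop(0.1, z))

  plain <- segment_shape("solid", outer, density = 1000)
  p1 <- segment_mass(plain)
  p2 <- mass_properties(loft_hoops(outer), 1000)
  expect_equal(p1$mass, p2$mass, tolerance = 1e-12)
  expect_equal(p1$com, p2$com, tolerance = 1e-12)
  expect_equal(p1$inertia, p2$inertia, tolerance = 1e-9)

  # concentric tube: both prisms are exact
  tube <- segment_shape("tube", outer, cavities = list(inner),
                        density = 1000, cavity_density = 0)
  a_out <- shoelace_area(outer[[1]]$vertices[, 1:2])
  a_in <- shoelace_area(inner[[1]]$vertices[, 1:2])
  expect_equal(segment_mass(tube)$mass,
               1000 * (a_out * 0.6 - a_in * 0.598), tolerance = 1e-10)

  # cavity at tissue density cancels
  same <- segment_shape("same", outer, cavities = list(inner),
                        density = 1000, cavity_density = 1000)
  expect_equal(segment_mass(same)$mass, p1$mass, tolerance = 1e-12)

  # cavity bigger than the outer solid is rejected
  big <- lapply(c(0.001, 0.599), function(z) octagon_hoop(0.35, z))
  expect_error(segment_mass(segment_shape("bad", outer,
                                          cavities = list(big))),
               "cavity volume")
})

test_that("segment_mass is additive over disjoint cavities", {
  outer <- lapply(c(0, 1), function(z) octagon_hoop(0.3, z))
  c1 <- lapply(c(0.1, 0.4), function(z)
    octagon_hoop(0.05, z, center_xy = c(0.1, 0)))
  c2 <- lapply(c(0.6, 0.9), function(z)
    octagon_hoop(0.05, z, center_xy = c(-0.1, 0)))
  both <- segment_mass(segment_shape("b", outer, cavities = list(c1, c2)))
  only1 <- segment_mass(segment_shape("1", outer, cavities = list(c1)))
  only2 <- segment_mass(segment_shape("2", outer, cavities = list(c2)))
  solid <- segment_mass(segment_shape("s", outer))
  expect_equal(both$mass, only1$mass + only2$mass - solid$mass,
               tolerance = 1e-10)
})

test_that("scaling hoop coordinates scales volume by s^3 and COM by s", {
  hoops <- list(octagon_hoop(0.2, 0), octagon_hoop(0.12, 0.3),
                octagon_hoop(0.18, 0.7))
  m1 <- loft_hoops(hoops)
  s <- 2.5
  scaled <- lapply(hoops, function(h) hoop(h$vertices * s, h$station * s))
  m2 <- loft_hoops(scaled)
  expect_equal(mesh_volume(m2), mesh_volume(m1) * s^3, tolerance = 1e-12)
  expect_equal(mass_properties(m2, 1)$com,
               mass_properties(m1, 1)$com * s, tolerance = 1e-12)
})

test_that("hoop stacks round-trip through YAML and CSV", {
  shapes <- list(
    torso = segment_shape("torso",
      lapply(c(0, 0.2, 0.4), function(z) octagon_hoop(0.15, z)),
      cavities = list(lapply(c(0.05, 0.35),
                             function(z) octagon_hoop(0.05, z))),
      density = 950, cavity_density = 0))
  yml <- file.path(tempdir(), "hoops.yaml")
  doc <- list(segments = lapply(shapes, function(s) list(
    name = s$name, density = s$density, cavity_density = s$cavity_density,
    hoops = lapply(s$outer, function(h)
      list(station = h$station,
           vertices = lapply(seq_len(8), function(i)
             as.numeric(h$vertices[i, ])))),
    cavities = lapply(s$cavities, function(st) lapply(st, function(h)
      list(station = h$station,
           vertices = lapply(seq_len(8), function(i)
             as.numeric(h$vertices[i, ]))))))))
  yaml::write_yaml(doc, yml, precision = 12)
  back <- read_hoops(yml)
  expect_equal(segment_mass(back$torso)$mass,
               segment_mass(shapes$torso)$mass, tolerance = 1e-9)

  csv <- file.path(tempdir(), "hoops.csv")
  rows <- do.call(rbind, lapply(seq_along(shapes$torso$outer), function(k) {
    h <- shapes$torso$outer[[k]]
    data.frame(segment = "torso", station = h$station, vertex = 1:8,
               x = h$vertices[, 1], y = h$vertices[, 2],
               z = h$vertices[, 3])
  }))
  utils::write.csv(rows, csv, row.names = FALSE)
  back2 <- read_hoops(csv)
  expect_equal(mesh_volume(loft_hoops(back2$torso$outer)),
               mesh_volume(loft_hoops(shapes$torso$outer)),
               tolerance = 1e-12)
})
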