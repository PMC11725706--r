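#' Cross-sectional hoop
#'
#' One station of a body-segment loft: a simple (non-self-intersecting)
#' planar octagon of 8 ordered 3D vertices, tagged with a scalar station used
#' only to order hoops along the segment's long axis. Hoops follow curved
#' body axes, so they need not be perpendicular to any global axis.
#'
#' @param vertices 8 x 3 matrix of ordered vertex coordinates (m).
#' @param station scalar position along the segment axis (m).
#' @return Object of class `"hoop"`.
#' @export
hoop <- function(vertices, station) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) != 8L || ncol(vertices) != 3L)
    stop("a hoop has exactly 8 vertices (8 x 3 matrix)")
  if (length(station) != 1L || !is.finite(station))
    stop("station must be a finite scalar")
  if (hoop_self_intersects(vertices))
    stop("hoop polygon is self-intersecting")
  structure(list(vertices = vertices, station = station), class = "hoop")
}

#' Regular octagon hoop in a z = station plane
#'
#' Convenience constructor used by the synthetic generators and in examples.
#'
#' @param radius circumradius of the octagon (m).
#' @param station z position, also used as the ordering station.
#' @param center_xy in-plane center (length 2).
#' @param rotation_deg in-plane rotation of the first vertex from +x.
#' @return A [hoop()].
#' @export
octagon_hoop <- function(radius, station, center_xy = c(0, 0),
                         rotation_deg = 0) {
  ang <- deg2rad(rotation_deg) + 2 * pi * (0:7) / 8
  hoop(cbind(center_xy[1L] + radius * cos(ang),
             center_xy[2L] + radius * sin(ang),
             station),
       station = station)
}

# Project onto the best-fit plane and test non-adjacent edge pairs.
hoop_self_intersects <- function(v) {
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  ev <- eigen(crossprod(vc), symmetric = TRUE)$vectors
  p <- vc %*% ev[, 1:2]   # in-plane coordinates
  n <- nrow(p)
  seg <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (segments_cross(p[seg[i, 1L], ], p[seg[i, 2L], ],
                         p[seg[j, 1L], ], p[seg[j, 2L], ]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a1, a2, b1, b2) {
  d1 <- cross2(b2 - b1, a1 - b1)
  d2 <- cross2(b2 - b1, a2 - b1)
  d3 <- cross2(a2 - a1, b1 - a1)
  d4 <- cross2(a2 - a1, b2 - a1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

#' Loft a stack of hoops into a watertight segment mesh
#'
#' Connects consecutive hoops by index correspondence (no twist): each side
#' quad is split into two triangles along the (i, i+1) diagonal,
#' deterministically, and end caps are triangulated as fans about the hoop
#' centroid. A stack of identical octagons extruded over a length h encloses
#' exactly (shoelace area) x h.
#'
#' @param hoops list of [hoop()] objects with strictly increasing stations.
#' @param cap_ends close the ends (default `TRUE`; open lofts are not
#'   watertight and fail validation).
#' @return A [trimesh()].
#' @export
loft_hoops <- function(hoops, cap_ends = TRUE) {
  if (!is.list(hoops) || length(hoops) < 2L)
    stop("need at least 2 hoops to loft")
  hoops <- lapply(hoops, function(h) {
    if (!inherits(h, "hoop")) h <- hoop(h$vertices, h$station)
    h
  })
  st <- vapply(hoops, function(h) h$station, 0)
  if (any(diff(st) <= 0))
    stop("hoop stations must be strictly increasing")
  k <- 8L
  nh <- length(hoops)
  verts <- do.call(rbind, lapply(hoops, function(h) h$vertices))
  idx <- function(ring, i) (ring - 1L) * k + ((i - 1L) %% k) + 1L
  tris <- vector("list", (nh - 1L) * 2L * k + if (cap_ends) 2L * k else 0L)
  t_at <- 0L
  for (ring in seq_len(nh - 1L)) {
    for (i in seq_len(k)) {
      a  <- idx(ring, i);      a2 <- idx(ring, i + 1L)
      b  <- idx(ring + 1L, i); b2 <- idx(ring + 1L, i + 1L)
      tris[[t_at + 1L]] <- c(a, a2, b2)
      tris[[t_at + 2L]] <- c(a, b2, b)
      t_at <- t_at + 2L
    }
  }
  if (cap_ends) {
    c_lo <- nrow(verts) + 1L
    c_hi <- nrow(verts) + 2L
    verts <- rbind(verts, colMeans(hoops[[1L]]$vertices),
                   colMeans(hoops[[nh]]$vertices))
    for (i in seq_len(k)) {
      tris[[t_at + 1L]] <- c(c_lo, idx(1L, i + 1L), idx(1L, i))
      tris[[t_at + 2L]] <- c(c_hi, idx(nh, i), idx(nh, i + 1L))
      t_at <- t_at + 2L
    }
  }
  trimesh(verts, do.call(rbind, tris), validate = cap_ends,
          normalize = TRUE)
}

#' Body-segment solid with optional air cavities
#'
#' Bundles an outer hoop stack with zero or more internal cavity stacks
#' (pharynx/trachea/lung spaces in the axial segments) plus densities.
#'
#' @param name segment name.
#' @param outer list of [hoop()] (>= 2).
#' @param cavities list of hoop stacks (each a list of >= 2 hoops).
#' @param density tissue density, kg/m^3 (default 1000, the aquatic-tissue
#'   convention).
#' @param cavity_density density inside cavities (default 0 = air),
#'   recycled across cavities.
#' @return Object of class `"segment_shape"`.
#' @export
segment_shape <- function(name, outer, cavities = list(), density = 1000,
                          cavity_density = 0) {
  if (length(outer) < 2L) stop("outer stack needs >= 2 hoops")
  if (density < 0) stop("density must be non-negative")
  cavity_density <- rep_len(cavity_density, max(1L, length(cavities)))
  structure(list(name = name, outer = outer, cavities = cavities,
                 density = density,
                 cavity_density = cavity_density[seq_along(cavities)]),
            class = "segment_shape")
}

#' Mass properties of a lofted segment with cavities
#'
#' The outer loft is integrated at the tissue density and each cavity is
#' applied as a signed correction at (cavity density - tissue density), so
#' mass = rho V_out + sum (rho_cav - rho) V_cav, with COM and inertia
#' composed from the same signed terms. A cavity at tissue density cancels
#' exactly.
#'
#' @param shape a [segment_shape()].
#' @return A `"mass_properties"` object.
#' @export
segment_mass <- function(shape) {
  stopifnot(inherits(shape, "segment_shape"))
  outer_mesh <- loft_hoops(shape$outer)
  terms <- list(list(mesh = outer_mesh, density = shape$density))
  v_out <- mesh_volume(outer_mesh)
  for (i in seq_along(shape$cavities)) {
    cm <- loft_hoops(shape$cavities[[i]])
    if (mesh_volume(cm) >= v_out)
      stop("cavity volume >= outer volume in segment '", shape$name, "'")
    terms[[length(terms) + 1L]] <-
      list(mesh = cm, density = shape$cavity_density[i] - shape$density)
  }
  combine_signed_terms(terms)
}

# Sum divergence-theorem integrals over meshes carrying signed densities.
combine_signed_terms <- function(terms) {
  mass <- 0
  first <- c(0, 0, 0)
  S <- matrix(0, 3, 3)
  for (tm in terms) {
    ints <- poly_integrals(tm$mesh)
    mass <- mass + tm$density * ints$volume
    first <- first + tm$density * ints$first
    S <- S + tm$density * ints$second
  }
  if (mass <= 0) stop("segment has non-positive total mass")
  com <- first / mass
  I0 <- sum(diag(S)) * diag(3) - S
  Icom <- I0 - mass * (sum(com^2) * diag(3) - outer(com, com))
  v_solid <- poly_integrals(terms[[1L]]$mesh)$volume
  new_mass_properties(mass, v_solid, com, (Icom + t(Icom)) / 2,
                      density = terms[[1L]]$density)
}

#' Read hoop stacks from YAML or CSV
#'
#' YAML schema: top-level `segments:`, each with `name`, optional `density`
#' and `cavity_density`, `hoops:` (list of `{station, vertices}` with 8
#' vertex triples), and optional `cavities:` (list of hoop lists). CSV
#' schema: long format with columns `segment, station, vertex, x, y, z`
#' (outer stacks only).
#'
#' @param path file path (`.yaml`/`.yml` or `.csv`).
#' @return Named list of [segment_shape()] objects.
#' @export
read_hoops <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- utils::read.csv(path)
    need <- c("segment", "station", "vertex", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("hoop CSV must have columns: ", paste(need, collapse = ", "))
    out <- lapply(split(tab, tab$segment), function(seg) {
      stacks <- lapply(split(seg, seg$station), function(hp) {
        hp <- hp[order(hp$vertex), ]
        hoop(as.matrix(hp[, c("x", "y", "z")]), hp$station[1L])
      })
      stacks <- stacks[order(vapply(stacks, function(h) h$station, 0))]
      segment_shape(seg$segment[1L], unname(stacks))
    })
    return(out)
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$segments)) stop("hoop YAML needs a 'segments' key")
  out <- list()
  for (seg in doc$segments) {
    parse_stack <- function(hs) lapply(hs, function(h)
      hoop(do.call(rbind, h$vertices), h$station))
    out[[seg$name]] <- segment_shape(
      seg$name, parse_stack(seg$hoops),
      cavities = if (is.null(seg$cavities)) list()
                 else lapply(seg$cavities, parse_stack),
      density = seg$density %||% 1000,
      cavity_density = seg$cavity_density %||% 0)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
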