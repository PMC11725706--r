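#' Exact mass properties of a watertight mesh
#'
#' Volume, center of mass and inertia tensor of the solid enclosed by a
#' watertight triangle mesh, by exact divergence-theorem integration over
#' signed origin tetrahedra (one per face). No discretization error: results
#' are closed-form polynomials in the vertex coordinates. The inertia tensor
#' is reported about the center of mass, in the mesh's own frame.
#'
#' @param mesh a [trimesh()] (validated and outward-oriented on construction).
#' @param density uniform density (kg/m^3), must be non-negative.
#' @return Object of class `"mass_properties"`: `mass` (kg), `volume` (m^3),
#'   `com` (m), `inertia` (3 x 3, kg m^2, about `com`), `density`.
#' @examples
#' p <- mass_properties(box_mesh(c(1, 1, 1)), density = 1000)
#' p$mass            # 1000 kg
#' diag(p$inertia)   # 1000/6 each
#' @export
mass_properties <- function(mesh, density) {
  if (!inherits(mesh, "trimesh")) stop("mesh must be a trimesh")
  if (length(density) != 1L || !is.finite(density) || density < 0)
    stop("density must be a single non-negative number (kg/m^3)")
  ints <- poly_integrals(mesh)
  if (ints$volume <= 0)
    stop("mesh encloses non-positive volume")
  volume <- ints$volume
  com <- ints$first / volume
  mass <- density * volume
  # second-moment matrix S = integral of r r^T; inertia about origin:
  # I0 = rho * (tr(S) I - S); shift to COM by inverse parallel axis.
  S <- ints$second
  I0 <- density * (sum(diag(S)) * diag(3) - S)
  Icom <- I0 - mass * (sum(com^2) * diag(3) - outer(com, com))
  Icom <- (Icom + t(Icom)) / 2
  new_mass_properties(mass, volume, com, Icom, density)
}

new_mass_properties <- function(mass, volume, com, inertia, density) {
  structure(list(mass = mass, volume = volume, com = as.numeric(com),
                 inertia = inertia, density = density),
            class = "mass_properties")
}

# Exact integrals of 1, x, and x_i x_j over the enclosed solid.
# Per signed tetra (0, a, b, c): V = det/6; int x = V (a+b+c)/4;
# int x_i x_j = V/20 (a_i a_j + b_i b_j + c_i c_j + s_i s_j), s = a+b+c.
poly_integrals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
          a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
          a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  vol6 <- det3
  s <- a + b + c3
  first <- colSums(vol6 * s) / 24      # (det/6) * s/4
  second <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    val <- sum(vol6 * (a[, i] * a[, j] + b[, i] * b[, j] +
                         c3[, i] * c3[, j] + s[, i] * s[, j])) / 120
    second[i, j] <- val
    second[j, i] <- val
  }
  list(volume = sum(vol6) / 6, first = first, second = second)
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("mass properties: m = %.6g kg, V = %.6g m^3, rho = %.6g kg/m^3\n",
              x$mass, x$volume, x$density))
  cat(sprintf("  COM (m): %.6g %.6g %.6g\n", x$com[1], x$com[2], x$com[3]))
  cat("  inertia about COM (kg m^2):\n")
  print(signif(x$inertia, 6))
  invisible(x)
}

#' Mass properties of a posed composite body
#'
#' Combines part mass properties after placing each part by a rigid
#' transform: total mass is the sum, the center of mass is the mass-weighted
#' mean of transformed part COMs, and inertia tensors are rotated and shifted
#' to the composite COM by the parallel-axis theorem.
#'
#' @param parts list of parts, each `list(props = <mass_properties>,
#'   transform = <4x4 rigid matrix>)`; the transform defaults to identity.
#' @return A `"mass_properties"` object (density field is the mass-weighted
#'   mean density, for reporting only).
#' @export
composite_properties <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L)
    stop("parts must be a nonempty list")
  parts <- lapply(parts, function(p) {
    if (inherits(p, "mass_properties")) p <- list(props = p)
    if (is.null(p$transform)) p$transform <- diag(4)
    if (!inherits(p$props, "mass_properties"))
      stop("each part needs a mass_properties object")
    if (!is_rigid(p$transform))
      stop("part transforms must be proper rigid motions")
    p
  })
  masses <- vapply(parts, function(p) p$props$mass, 0)
  total <- sum(masses)
  if (abs(total) < .Machine$double.eps * 1e3)
    stop("total mass is zero; composite COM undefined")
  coms <- t(vapply(parts, function(p)
    as.numeric(apply_transform(p$transform, p$props$com)), numeric(3)))
  com <- colSums(coms * masses) / total
  inertia <- matrix(0, 3, 3)
  for (k in seq_along(parts)) {
    R <- parts[[k]]$transform[1:3, 1:3]
    Irot <- R %*% parts[[k]]$props$inertia %*% t(R)
    d <- coms[k, ] - com
    inertia <- inertia +
      Irot + masses[k] * (sum(d^2) * diag(3) - outer(d, d))
  }
  volume <- sum(vapply(parts, function(p) p$props$volume, 0))
  new_mass_properties(total, volume, com, (inertia + t(inertia)) / 2,
                      density = if (volume > 0) total / volume else NA_real_)
}

#' Mirror mass properties across the midsagittal plane
#'
#' Reflection across y = 0 (the model's midsagittal plane in the global
#' anatomical frame): mass and volume preserved, COM reflected, inertia
#' conjugated by the reflection matrix. Applying it twice is the identity.
#'
#' @param props a `"mass_properties"` object.
#' @param plane only `"sagittal"` is supported.
#' @return Mirrored `"mass_properties"`.
#' @export
mirror_body <- function(props, plane = "sagittal") {
  plane <- match.arg(plane, "sagittal")
  S <- diag(c(1, -1, 1))
  new_mass_properties(props$mass, props$volume, S %*% props$com,
                      S %*% props$inertia %*% S, props$density)
}

#' Write mass properties to JSON or CSV
#'
#' @param props a `"mass_properties"` object (or list of them, named).
#' @param path output file; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_mass_properties <- function(props, path) {
  if (inherits(props, "mass_properties")) props <- list(body = props)
  ext <- tolower(tools::file_ext(path))
  rows <- lapply(names(props), function(nm) {
    p <- props[[nm]]
    data.frame(name = nm, mass_kg = p$mass, volume_m3 = p$volume,
               com_x_m = p$com[1], com_y_m = p$com[2], com_z_m = p$com[3],
               ixx = p$inertia[1, 1], iyy = p$inertia[2, 2],
               izz = p$inertia[3, 3], ixy = p$inertia[1, 2],
               ixz = p$inertia[1, 3], iyz = p$inertia[2, 3],
               density_kg_m3 = p$density)
  })
  tab <- do.call(rbind, rows)
  if (ext == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    out <- lapply(props, function(p)
      list(mass_kg = p$mass, volume_m3 = p$volume, com_m = p$com,
           inertia_kg_m2 = p$inertia, density_kg_m3 = p$density))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(path)
}
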