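#' Whole-body center of mass in a pose
#'
#' Composites posed segment mass properties and reports the COM relative to
#' the posed acetabular midpoint, in the global anatomical frame: the
#' craniad offset is the +X difference and the ventrad offset the -Z
#' difference. The craniad offset is also reported dimensionless, divided
#' by the gleno-acetabular distance.
#'
#' @param model a [body_model()] in which every segment carries mass
#'   properties (directly, via a [segment_shape()], or via a mesh plus
#'   density), with landmarks `acetabulum` and (for the dimensionless
#'   offset) `glenoid`.
#' @param pose named pose list (degrees); ROM is not enforced here.
#' @return Object of class `"com_report"`: `com` (m, global), `craniad_m`,
#'   `ventrad_m`, `craniad_per_ga`, `ga_m`, `mass_kg`, and the composite
#'   `"mass_properties"` in `$properties`.
#' @export
whole_body_com <- function(model, pose = list()) {
  tf <- forward_kinematics(model, pose)
  parts <- list()
  for (nm in names(model$segments)) {
    props <- segment_properties(model$segments[[nm]], nm)
    parts[[nm]] <- list(props = props, transform = tf[[nm]])
  }
  total <- composite_properties(parts)
  if (is.null(model$landmarks$acetabulum))
    stop("model needs an 'acetabulum' landmark")
  acet <- posed_landmark(model, "acetabulum", tf)
  ga <- if (!is.null(model$landmarks$glenoid)) {
    glen <- posed_landmark(model, "glenoid", tf)
    sqrt(sum((glen - acet)^2))
  } else NA_real_
  craniad <- total$com[1L] - acet[1L]
  ventrad <- -(total$com[3L] - acet[3L])
  structure(list(com = total$com, craniad_m = craniad, ventrad_m = ventrad,
                 craniad_per_ga = craniad / ga, ga_m = ga,
                 mass_kg = total$mass, properties = total),
            class = "com_report")
}

segment_properties <- function(seg, name) {
  if (!is.null(seg$mass_props)) return(seg$mass_props)
  if (!is.null(seg$shape)) return(segment_mass(seg$shape))
  if (!is.null(seg$mesh) && !is.null(seg$density))
    return(mass_properties(seg$mesh, seg$density))
  stop("segment '", name, "' has no mass properties, shape, or ",
       "mesh + density")
}

posed_landmark <- function(model, name, transforms) {
  lm <- model$landmarks[[name]]
  as.numeric(apply_transform(transforms[[lm$segment]], lm$point))
}

#' @export
print.com_report <- function(x, ...) {
  cat(sprintf("whole-body mass %.4g kg\n", x$mass_kg))
  cat(sprintf("COM offset from acetabula: %.4g m craniad, %.4g m ventrad\n",
              x$craniad_m, x$ventrad_m))
  if (is.finite(x$craniad_per_ga))
    cat(sprintf("dimensionless craniad offset (per GA %.4g m): %.4g\n",
                x$ga_m, x$craniad_per_ga))
  invisible(x)
}

#' Static bipedal-feasibility test
#'
#' Sagittal statics only: standing bipedally is feasible iff the craniad
#' COM offset falls (inclusively) inside the feet's craniocaudal support
#' interval, both measured from the acetabula. The margin is the distance
#' to the nearest support boundary, negative by the shortfall when
#' infeasible.
#'
#' @param report a `"com_report"` (or a bare craniad offset in m).
#' @param support `c(x_min, x_max)` support interval relative to the
#'   acetabula (m), `x_min < x_max`.
#' @return List: `feasible` (logical), `margin_m`, `craniad_m`, `support`.
#' @export
bipedal_feasibility <- function(report, support) {
  craniad <- if (inherits(report, "com_report")) report$craniad_m
             else as.numeric(report)
  if (length(support) != 2L || !(support[1L] < support[2L]))
    stop("support must be c(x_min, x_max) with x_min < x_max")
  margin <- min(craniad - support[1L], support[2L] - craniad)
  list(feasible = margin >= 0, margin_m = margin, craniad_m = craniad,
       support = support)
}

#' Allometric body mass from stylopodial circumferences
#'
#' Scaling regression on humeral plus femoral minimal diaphyseal
#' circumference: log10 BM[g] = 2.749 log10(Ch + Cf [mm]) - 1.104, with a
#' +/- 25.6% prediction-error band. For circumferences of 39 and 66 mm
#' this yields 28.33 kg.
#'
#' @param c_humerus,c_femur minimal diaphyseal circumferences (mm), > 0.
#' @return List: `mass_kg`, `lower_kg`, `upper_kg` (the 25.6% band),
#'   `pe_fraction`.
#' @examples
#' allometric_mass(39, 66)$mass_kg   # 28.33
#' @export
allometric_mass <- function(c_humerus, c_femur) {
  if (any(c(c_humerus, c_femur) <= 0))
    stop("circumferences must be > 0 (mm)")
  bm_g <- 10^(2.749 * log10(c_humerus + c_femur) - 1.104)
  bm <- bm_g / 1000
  list(mass_kg = bm, lower_kg = bm * (1 - 0.256), upper_kg = bm * (1 + 0.256),
       pe_fraction = 0.256)
}

#' Inverse of the stylopodial mass equation
#'
#' Combined circumference (mm) giving a stated body mass; round-trips with
#' [allometric_mass()] exactly.
#'
#' @param mass_kg body mass (kg), > 0.
#' @return Combined humeral + femoral circumference (mm).
#' @export
allometric_circumference <- function(mass_kg) {
  if (mass_kg <= 0) stop("mass must be > 0")
  10^((log10(mass_kg * 1000) + 1.104) / 2.749)
}

#' Limb-chain lengths and gleno-acetabular distance
#'
#' Sums consecutive joint-to-joint distances along each declared chain in
#' the reference pose; the chain may end at a named landmark. The GA
#' distance is the acetabulum-glenoid landmark separation.
#'
#' @param model a [body_model()] with `chains` declared (typically
#'   `forelimb` and `hindlimb`).
#' @return List: one length (m) per chain, plus `ga_m`.
#' @export
limb_lengths <- function(model) {
  if (length(model$chains) == 0L)
    stop("model declares no limb chains")
  tf <- forward_kinematics(model, list())
  out <- list()
  for (nm in names(model$chains)) {
    ch <- model$chains[[nm]]
    pts <- lapply(ch$joints, function(jn) {
      j <- model$joints[[jn]] %||% stop("chain '", nm,
                                        "' names unknown joint '", jn, "'")
      j$origin
    })
    if (!is.null(ch$end_landmark))
      pts[[length(pts) + 1L]] <- posed_landmark(model, ch$end_landmark, tf)
    if (length(pts) < 2L) stop("chain '", nm, "' has fewer than 2 points")
    pm <- do.call(rbind, pts)
    out[[nm]] <- sum(sqrt(rowSums(diff(pm)^2)))
  }
  out$ga_m <- if (!is.null(model$landmarks$acetabulum) &&
                  !is.null(model$landmarks$glenoid)) {
    sqrt(sum((posed_landmark(model, "glenoid", tf) -
                posed_landmark(model, "acetabulum", tf))^2))
  } else NA_real_
  out
}
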