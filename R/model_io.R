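#' Path to a shipped fixture file
#'
#' @param file fixture file name (e.g. `"riojasuchus_rom.yaml"`); empty to
#'   list available fixtures.
#' @return Full path.
#' @export
paleomech_example <- function(file = "") {
  if (!nzchar(file))
    return(dir(system.file("extdata", package = "paleomech")))
  p <- system.file("extdata", file, package = "paleomech")
  if (!nzchar(p)) stop("no shipped fixture named '", file, "'")
  p
}

#' Load a body model from YAML
#'
#' Schema: `segments` (name, optional mesh path relative to the YAML file,
#' density), `joints` (name, parent, child, origin, optional axes with x/y/z
#' columns, dof, rom, cartilage_offset, articular_patch), `muscles`
#' (acronym, points with segment + xyz, wraps), `landmarks`, `chains`,
#' `poses`. All cross-references are validated; a dangling segment or a
#' missing mesh file is an error naming the offending field.
#'
#' @param path model YAML path.
#' @return A fully linked [body_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- yaml::read_yaml(path)
  base <- dirname(path)
  if (is.null(doc$segments)) stop("model YAML: missing 'segments'")
  segments <- list()
  for (s in doc$segments) {
    if (is.null(s$name)) stop("model YAML: segments[].name missing")
    seg <- list(density = s$density %||% 1000)
    if (!is.null(s$mesh)) {
      mp <- if (file.exists(s$mesh)) s$mesh else file.path(base, s$mesh)
      if (!file.exists(mp))
        stop("segments['", s$name, "'].mesh: file not found: ", s$mesh)
      seg$mesh <- read_obj(mp)
      seg$mesh_file <- s$mesh
    }
    segments[[s$name]] <- seg
  }
  joints <- list()
  for (j in doc$joints %||% list()) {
    if (is.null(j$name)) stop("model YAML: joints[].name missing")
    ja <- fix_yaml_bool_names(j$axes)
    axes <- if (is.null(ja)) diag(3)
            else cbind(as.numeric(ja$x), as.numeric(ja$y),
                       as.numeric(ja$z))
    rom <- lapply(fix_yaml_bool_names(j$rom %||% list()), as.numeric)
    dof <- unlist(j$dof) %||% "z"
    dof[dof %in% c("TRUE", "FALSE", "yes", "no")] <- "y"
    joints[[j$name]] <- joint_def(
      j$name, j$parent, j$child, as.numeric(j$origin), axes,
      dof = dof, rom = rom,
      cartilage_offset = as.numeric(j$cartilage_offset %||% c(0, 0, 0)),
      articular_patch = j$articular_patch)
  }
  muscles <- list()
  for (m in doc$muscles %||% list()) {
    pts <- do.call(rbind, lapply(m$points, function(p)
      data.frame(x = p$xyz[[1L]], y = p$xyz[[2L]], z = p$xyz[[3L]],
                 segment = p$segment)))
    wraps <- lapply(m$wraps %||% list(), function(w)
      wrap_surface(w$kind, w$segment, as.numeric(w$origin), w$radius,
                   axis = as.numeric(w$axis %||% c(0, 0, 1)),
                   side = w$side %||% "short"))
    muscles[[m$acronym]] <- muscle_path(m$acronym, pts, wraps,
                                        inference = m$inference)
  }
  landmarks <- lapply(doc$landmarks %||% list(), function(l)
    list(point = as.numeric(l$point), segment = l$segment))
  chains <- lapply(doc$chains %||% list(), function(ch)
    list(joints = unlist(ch$joints), end_landmark = ch$end_landmark))
  poses <- lapply(doc$poses %||% list(), function(p)
    lapply(p, function(a) {
      a <- unlist(fix_yaml_bool_names(as.list(a)))
      a
    }))
  body_model(segments, joints, muscles, landmarks, chains, poses)
}

#' Save a body model as YAML (plus OBJ meshes)
#'
#' Inverse of [load_model()]; segment meshes, if present, are written as
#' OBJ files next to the YAML.
#'
#' @param model a [body_model()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  base <- dirname(path)
  doc <- list(segments = list(), joints = list(), muscles = list(),
              landmarks = list(), chains = list(), poses = list())
  for (nm in names(model$segments)) {
    s <- model$segments[[nm]]
    entry <- list(name = nm, density = s$density)
    if (!is.null(s$mesh)) {
      mf <- paste0(nm, ".obj")
      write_obj(s$mesh, file.path(base, mf))
      entry$mesh <- mf
    }
    doc$segments[[length(doc$segments) + 1L]] <- entry
  }
  for (j in model$joints) {
    doc$joints[[length(doc$joints) + 1L]] <- list(
      name = j$name, parent = j$parent, child = j$child,
      origin = as.numeric(j$origin - j$cartilage_offset),
      axes = list(x = j$axes[, 1L], y = j$axes[, 2L], z = j$axes[, 3L]),
      dof = as.list(names(j$dof)[j$dof]),
      rom = lapply(j$rom, as.numeric),
      cartilage_offset = j$cartilage_offset,
      articular_patch = j$articular_patch)
  }
  for (m in model$muscles) {
    doc$muscles[[length(doc$muscles) + 1L]] <- list(
      acronym = m$acronym,
      points = lapply(seq_len(nrow(m$points)), function(i)
        list(segment = m$points$segment[i],
             xyz = as.numeric(m$points[i, c("x", "y", "z")]))),
      wraps = lapply(m$wraps, function(w)
        list(kind = w$kind, segment = w$segment, origin = w$origin,
             radius = w$radius, axis = w$axis, side = w$side)),
      inference = m$inference)
  }
  doc$landmarks <- model$landmarks
  doc$chains <- model$chains
  doc$poses <- lapply(model$poses, function(p) lapply(p, as.list))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

# YAML 1.1 parses bare y/n keys as booleans; map them back to the "y" DOF.
fix_yaml_bool_names <- function(x) {
  if (is.null(x)) return(x)
  nm <- names(x)
  nm[nm %in% c("TRUE", "yes")] <- "y"
  names(x) <- nm
  x
}

#' Span of a declared ROM interval
#'
#' @param model a [body_model()].
#' @param joint,dof joint name and DOF.
#' @return `max - min` in degrees.
#' @export
rom_span <- function(model, joint, dof = "z") {
  lim <- model$joints[[joint]]$rom[[dof]]
  if (is.null(lim)) stop("no ROM declared for ", joint, "/", dof)
  diff(range(lim))
}

#' Load the shipped muscle attachment table
#'
#' The hindlimb muscle origin/insertion topology (bone + region per
#' attachment, with levels of inference), transcribed from the published
#' reconstruction table.
#'
#' @param path CSV path; defaults to the shipped
#'   `riojasuchus_muscles.csv`.
#' @return Data frame: `acronym`, `muscle`, `origin`, `insertion`,
#'   `origin_level`, `insertion_level`.
#' @export
load_muscle_table <- function(path = paleomech_example(
                                "riojasuchus_muscles.csv")) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("acronym", "muscle", "origin", "insertion", "origin_level",
            "insertion_level")
  if (!all(need %in% names(tab)))
    stop("muscle table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$acronym))
    stop("muscle acronyms must be unique")
  tab
}

#' Load a YAML fixture (summary measurements, feature records)
#'
#' @param path YAML path.
#' @return Parsed list.
#' @export
load_fixture_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Command-line pipeline driver
#'
#' Thin dispatch over the package's functions; the shipped script
#' `inst/cli/paleomech` forwards `commandArgs(TRUE)` here. Subcommands:
#' `mass-props`, `com`, `biped-check`, `mma-sweep`, `rom-scan`,
#' `classify`, `allometric-mass`, `make-synthetic`. Angles are degrees,
#' lengths meters, masses kg in all files and options. Each run logs a
#' JSON line (version, seed, config hash) to stderr.
#'
#' @param args character vector, e.g.
#'   `c("allometric-mass", "--ch", "39", "--cf", "66")`.
#' @return The subcommand's result, invisibly.
#' @export
run_pipeline <- function(args) {
  if (length(args) == 0L)
    stop("usage: paleomech <subcommand> [--option value ...]")
  cmd <- args[1L]
  opt <- parse_cli_options(args[-1L])
  log_run(cmd, opt)
  res <- switch(cmd,
    "allometric-mass" = cli_allometric(opt),
    "mass-props" = cli_mass_props(opt),
    "com" = cli_com(opt),
    "biped-check" = cli_biped(opt),
    "mma-sweep" = cli_mma(opt),
    "rom-scan" = cli_rom_scan(opt),
    "classify" = cli_classify(opt),
    "make-synthetic" = cli_make_synthetic(opt),
    stop("unknown subcommand '", cmd, "'"))
  invisible(res)
}

parse_cli_options <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --option, got '", args[i], "'")
    key <- substring(args[i], 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}

opt_num <- function(opt, key, default = NULL) {
  v <- opt[[key]] %||% default
  if (is.null(v)) stop("missing required option --", key)
  as.numeric(v)
}
opt_chr <- function(opt, key, default = NULL) {
  v <- opt[[key]] %||% default
  if (is.null(v)) stop("missing required option --", key)
  as.character(v)
}

log_run <- function(cmd, opt) {
  cfg <- opt[["model"]] %||% opt[["obj"]] %||% opt[["train"]]
  hash <- if (!is.null(cfg) && file.exists(cfg))
    unname(tools::md5sum(cfg)) else NA_character_
  line <- jsonlite::toJSON(list(
    tool = "paleomech", version = as.character(utils::packageVersion("paleomech")),
    subcommand = cmd, seed = opt[["seed"]] %||% NA,
    config_hash = hash), auto_unbox = TRUE, na = "null")
  message(line)
}

cli_allometric <- function(opt) {
  res <- allometric_mass(opt_num(opt, "ch"), opt_num(opt, "cf"))
  cat(sprintf("%.2f kg (+/- %.1f%% PE: %.2f-%.2f kg)\n", res$mass_kg,
              100 * res$pe_fraction, res$lower_kg, res$upper_kg))
  res
}

cli_mass_props <- function(opt) {
  mesh <- read_obj(opt_chr(opt, "obj"),
                   scale = opt_num(opt, "scale", 1))
  props <- mass_properties(mesh, opt_num(opt, "density", 1000))
  out <- opt[["out"]]
  if (!is.null(out)) write_mass_properties(props, out)
  print(props)
  props
}

cli_com <- function(opt) {
  model <- load_model(opt_chr(opt, "model"))
  pose_name <- opt[["pose"]]
  pose <- if (is.null(pose_name)) list()
          else model$poses[[pose_name]] %||%
            stop("no preset pose '", pose_name, "'")
  rep <- whole_body_com(model, pose)
  print(rep)
  out <- opt[["out"]]
  if (!is.null(out))
    jsonlite::write_json(rep[c("com", "craniad_m", "ventrad_m",
                               "craniad_per_ga", "ga_m", "mass_kg")],
                         out, auto_unbox = TRUE, digits = NA)
  rep
}

cli_biped <- function(opt) {
  model <- load_model(opt_chr(opt, "model"))
  pose_name <- opt[["pose"]]
  pose <- if (is.null(pose_name)) list() else model$poses[[pose_name]]
  rep <- whole_body_com(model, pose)
  verdict <- bipedal_feasibility(rep, c(opt_num(opt, "support-min"),
                                        opt_num(opt, "support-max")))
  cat(sprintf("bipedal support %s: COM %.4g m craniad, margin %.4g m\n",
              if (verdict$feasible) "FEASIBLE" else "infeasible",
              verdict$craniad_m, verdict$margin_m))
  verdict
}

cli_mma <- function(opt) {
  model <- if (!is.null(opt[["synthetic-seed"]]))
    make_skeleton(opt_num(opt, "synthetic-seed"))$model
  else load_model(opt_chr(opt, "model"))
  grid <- seq(opt_num(opt, "from"), opt_num(opt, "to"),
              by = opt_num(opt, "step", 5))
  curve <- mma_sweep(model, opt_chr(opt, "muscle"), opt_chr(opt, "joint"),
                     opt_chr(opt, "dof", "z"), grid,
                     h_deg = opt_num(opt, "h", 0.25))
  out <- opt[["out"]]
  if (!is.null(out)) write_mma_csv(curve, out)
  curve
}

cli_rom_scan <- function(opt) {
  model <- if (!is.null(opt[["synthetic-seed"]]))
    make_skeleton(opt_num(opt, "synthetic-seed"))$model
  else load_model(opt_chr(opt, "model"))
  lim <- rom_scan(model, opt_chr(opt, "joint"), opt_chr(opt, "dof", "z"),
                  step_deg = opt_num(opt, "step", 1),
                  gap_m = opt_num(opt, "gap", Inf))
  cat(sprintf("estimated ROM: [%g, %g] deg\n", lim[1L], lim[2L]))
  out <- opt[["out"]]
  if (!is.null(out))
    jsonlite::write_json(list(joint = opt_chr(opt, "joint"),
                              min_deg = lim[1L], max_deg = lim[2L]),
                         out, auto_unbox = TRUE, digits = NA)
  lim
}

cli_classify <- function(opt) {
  train <- utils::read.csv(opt_chr(opt, "train"))
  if (!"set" %in% names(train)) train$set <- 1L
  target <- utils::read.csv(opt_chr(opt, "target"))
  sets <- split(train, train$set)
  vote <- vote_over_trainings(unname(sets), target[1L, , drop = FALSE])
  cat(sprintf("bipedal votes: %d / %d\n", vote$votes, vote$n_sets))
  out <- opt[["out"]]
  if (!is.null(out))
    jsonlite::write_json(vote, out, auto_unbox = TRUE, digits = NA)
  vote
}

cli_make_synthetic <- function(opt) {
  seed <- opt_num(opt, "seed")
  out <- opt_chr(opt, "out")
  write_synthetic_bundle(make_skeleton(seed), out)
}

#' Write a synthetic-skeleton bundle to a directory
#'
#' OBJ meshes, model YAML and ground-truth JSON; byte-identical for the
#' same seed.
#'
#' @param skeleton a `"synthetic_skeleton"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(skeleton, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_model(skeleton$model, file.path(dir, "model.yaml"))
  tr <- skeleton$truth
  tr$muscle_closed_form <- if (!is.null(tr$muscle_closed_form))
    as.list(tr$muscle_closed_form)
  jsonlite::write_json(c(list(seed = skeleton$seed), tr),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
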