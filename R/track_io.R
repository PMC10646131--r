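# Tidy CSV representations of condylar tracks, rotation profiles, the
# landmark sidecar and JSON reports, plus the YAML run configuration.

#' Read / write condylar tracks as tidy CSV
#'
#' Columns: `knee_id`, `group`, `activity`, `flexion_deg`, `ap_med_mm`,
#' `ml_med_mm`, `ap_lat_mm`, `ml_lat_mm`, `standardized` (0/1), `repeats`,
#' `reference`. One observation (schedule angle) per row.
#'
#' @param track a [condylar_track()].
#' @param path file path.
#' @param knee_id,group identifiers stored with each row.
#' @return `read_track()` returns a [condylar_track()] (with `knee_id` and
#'   `group` attributes); `write_track()` returns `path` invisibly.
#' @export
write_track <- function(track, path, knee_id = "knee", group = NA_character_) {
  df <- data.frame(knee_id = knee_id, group = group,
                   activity = attr(track, "activity"),
                   flexion_deg = track$flexion_deg,
                   ap_med_mm = track$ap_med, ml_med_mm = track$ml_med,
                   ap_lat_mm = track$ap_lat, ml_lat_mm = track$ml_lat,
                   standardized = as.integer(isTRUE(attr(track, "standardized"))),
                   repeats = attr(track, "repeats"),
                   reference = attr(track, "reference"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  if (!file.exists(path)) kt_format_error(paste("no such track file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flexion_deg", "ap_med_mm", "ml_med_mm", "ap_lat_mm", "ml_lat_mm")
  if (!all(need %in% names(df)))
    kt_format_error(paste("track CSV is missing columns:",
                          paste(setdiff(need, names(df)), collapse = ", ")))
  tr <- condylar_track(
    data.frame(flexion_deg = df$flexion_deg, ap_med = df$ap_med_mm,
               ml_med = df$ml_med_mm, ap_lat = df$ap_lat_mm,
               ml_lat = df$ml_lat_mm),
    reference = df$reference[1L] %||% "native_resection_plane",
    activity = df$activity[1L] %||% NA_character_,
    repeats = df$repeats[1L] %||% 1L,
    standardized = isTRUE(df$standardized[1L] == 1L))
  attr(tr, "knee_id") <- df$knee_id[1L]
  attr(tr, "group") <- df$group[1L]
  tr
}

#' Read / write rotation profiles as CSV
#'
#' Writes the per-angle rotation table to `path` and the arc table to the
#' same name with an `_arcs` suffix.
#'
#' @param profile a `rotation_profile`.
#' @param path file path (`.csv`).
#' @return `read_profile()` returns a `rotation_profile`; `write_profile()`
#'   returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(cbind(activity = profile$activity, profile$rotation),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(profile$arcs, arcs_path(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

arcs_path <- function(path)
  file.path(dirname(path), paste0(tools::file_path_sans_ext(basename(path)),
                                  "_arcs.", tools::file_ext(path)))

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  rot <- utils::read.csv(path, stringsAsFactors = FALSE)
  arcs <- utils::read.csv(arcs_path(path), stringsAsFactors = FALSE)
  structure(list(activity = rot$activity[1L],
                 schedule = rot$flexion_deg,
                 rotation = rot[c("flexion_deg", "rotation_deg")],
                 arcs = arcs,
                 max_flexion_rotation = sum(arcs$delta_deg)),
            class = "rotation_profile")
}

#' Write the landmark sidecar for a knee model
#'
#' JSON record of the analytic landmarks and patch vertex labels so a model
#' written as mesh files can be re-analyzed without re-deriving patches.
#'
#' @param model a `knee_model` or `tka_model`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(model, path) {
  lm <- model$landmarks
  enc <- lapply(lm, function(x) {
    if (inherits(x, "kt_plane")) list(point = x$point, normal = x$normal) else x
  })
  slots <- intersect(c("femur", "tibia", "baseplate"), names(model))
  labels <- lapply(slots, function(m) model[[m]]$labels)
  # label keys follow the on-disk body names
  names(labels) <- ifelse(slots == "femur" & model$type == "tka",
                          "femoral_component", slots)
  jsonlite::write_json(list(type = model$type, side = model$spec$side,
                            landmarks = enc, labels = labels),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a knee model from mesh files plus the landmark sidecar
#'
#' @param dir directory containing `femur.stl`, `tibia.stl` (native) or
#'   `femoral_component.stl`, `baseplate.stl` (TKA), and `landmarks.json`.
#' @return A `knee_model` / `tka_model`.
#' @export
read_knee_model <- function(dir) {
  side <- file.path(dir, "landmarks.json")
  if (!file.exists(side)) kt_format_error(paste("no landmark sidecar in", dir))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  lm <- meta$landmarks
  for (nm in names(lm)) {
    x <- lm[[nm]]
    if (is.list(x) && !is.null(x$normal)) lm[[nm]] <- plane(x$point, x$normal)
  }
  load_mesh <- function(body) {
    m <- read_mesh(file.path(dir, paste0(body, ".stl")))
    lb <- meta$labels[[body]]
    if (!is.null(lb)) m$labels <- lapply(lb, as.integer)
    m
  }
  if (identical(meta$type, "tka")) {
    model <- list(femur = load_mesh("femoral_component"),
                  baseplate = load_mesh("baseplate"),
                  landmarks = lm, spec = list(side = meta$side), type = "tka")
    class(model) <- c("tka_model", "knee_model")
  } else {
    model <- list(femur = load_mesh("femur"), tibia = load_mesh("tibia"),
                  landmarks = lm, spec = list(side = meta$side), type = "native")
    class(model) <- "knee_model"
  }
  model
}

#' Write a knee model's meshes and landmark sidecar
#'
#' @param model a `knee_model` / `tka_model`.
#' @param dir output directory (created if needed).
#' @param binary write binary STL (default) or ASCII.
#' @return `dir`, invisibly.
#' @export
write_knee_model <- function(model, dir, binary = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bodies <- if (model$type == "tka") {
    c(femur = "femoral_component", baseplate = "baseplate")
  } else {
    c(femur = "femur", tibia = "tibia")
  }
  for (slot in names(bodies))
    write_mesh(model[[slot]], file.path(dir, paste0(bodies[[slot]], ".stl")),
               binary = binary)
  write_landmarks(model, file.path(dir, "landmarks.json"))
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' Fields (all optional unless a stage needs them): `activity`, `schedule`,
#' `resection` (list of [resection_params()] fields), `standardization`,
#' `noise` (list of [noise_spec()] fields), `seed`, `test_kind`, `power`
#' (list of [power_spec()] fields), `paths`.
#'
#' @param path YAML file.
#' @return Named list with a `config_hash` attribute (MD5 of the file).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) kt_format_error(paste("no such config file:", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$noise) && is.null(cfg$seed) && is.null(cfg$noise$seed))
    kt_parameter_error("a seed is mandatory when a stochastic stage is configured")
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}
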