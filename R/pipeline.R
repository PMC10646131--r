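# End-to-end analysis: reference frames from the meshes, per-frame relative
# poses, flexion matching against the activity schedule, lowest-point
# condylar tracks, rotation profiles, and the simulate/analyze/stats/power
# entry points used by the command-line wrapper.

#' Build the tibial reference frames for a knee
#'
#' For a native knee: femoral sagittal frame, medial plateau plane,
#' simulated resection plane and the tibial bounding-box frame. For a TKA
#' knee: the baseplate bounding-box frame. The reference plane for lowest
#' points is the resection plane (native) or the baseplate top surface
#' (TKA).
#'
#' @param model a `knee_model` or `tka_model` (right-knee convention).
#' @param resection a [resection_params()].
#' @return List with `frame` (a `tibial_frame`), `reference` (a [plane()]),
#'   and for native knees `sagittal`, `plateau_plane`, `resection`.
#' @export
knee_reference_frames <- function(model, resection = resection_params()) {
  if (model$type == "tka") {
    fr <- baseplate_frame(model)
    return(list(frame = fr, reference = fr$reference_plane))
  }
  sagittal <- femoral_sagittal_frame(model$femur)
  plateau <- medial_plateau_plane(model$tibia, sagittal)
  res <- simulate_resection_plane(model, resection, sagittal)
  fr <- tibial_frame(res, model$tibia, sagittal)
  list(frame = fr, reference = plane(res$point, res$normal),
       sagittal = sagittal, plateau_plane = plateau, resection = res)
}

# Flexion per frame: stored annotation when present, else recomputed from
# the anatomic axes transformed by the relative pose.
frame_flexion <- function(model, rel_poses, stored) {
  if (!anyNA(stored)) return(stored)
  lm <- model$landmarks
  if (is.null(lm$femur_shaft_axis) || is.null(lm$tibia_shaft_axis))
    kt_parameter_error(paste(
      "pose sequence lacks flexion annotations and the model has no shaft",
      "axes to recompute them from"))
  fdir <- lm$femur_shaft_axis$dir
  tdir <- lm$tibia_shaft_axis$dir
  vapply(rel_poses, function(M)
    flexion_angle(as.numeric(M[1:3, 1:3] %*% fdir), tdir), numeric(1L))
}

# Match each schedule angle to frames: exact, else linear interpolation
# between the bracketing frames, else nearest frame within 5 deg.
match_schedule <- function(flex, schedule, tol_nearest = 5) {
  lapply(schedule, function(f) {
    hit <- which(abs(flex - f) < 1e-9)
    if (length(hit)) return(list(i = hit[1L], j = hit[1L], w = 1))
    above <- which(flex > f); below <- which(flex < f)
    if (length(above) && length(below)) {
      i <- above[which.min(flex[above] - f)]
      j <- below[which.min(f - flex[below])]
      return(list(i = i, j = j, w = (f - flex[j]) / (flex[i] - flex[j])))
    }
    k <- which.min(abs(flex - f))
    if (abs(flex[k] - f) > tol_nearest)
      kt_parameter_error(sprintf(
        "no pose frame within %g deg of schedule angle %g deg", tol_nearest, f))
    list(i = k, j = k, w = 1)
  })
}

#' Analyze one knee: poses to condylar track and rotation profile
#'
#' Runs the lowest-point pipeline on a pose sequence: builds the tibial
#' reference frames, computes the femur-relative-to-tibia pose and flexion
#' angle per frame, matches the activity schedule (exact frame, else linear
#' interpolation between bracketing frames, else nearest within 5 deg),
#' extracts the condylar (A-P, M-L) positions, and derives the rotation
#' profile and the standardized track. Left-knee models and poses are
#' mirrored into the right-knee convention before analysis.
#'
#' @param model a `knee_model` or `tka_model`.
#' @param poses a [pose_sequence()] containing the femoral and tibial body
#'   rows.
#' @param activity `"step_up"` or `"chair_rise"`.
#' @param schedule optional schedule override (deg).
#' @param resection a [resection_params()] (native knees).
#' @param frames optional precomputed [knee_reference_frames()] (reused
#'   across registration repeats).
#' @return List with `track` (non-standardized [condylar_track()]),
#'   `track_std` (standardized), `profile` (a `rotation_profile`) and
#'   `frames`.
#' @export
analyze_knee <- function(model, poses, activity = c("step_up", "chair_rise"),
                         schedule = NULL, resection = resection_params(),
                         frames = NULL) {
  activity <- match.arg(activity)
  schedule <- schedule %||% activity_schedule(activity)
  if (!is.null(model$spec$side) && identical(model$spec$side, "left")) {
    model <- mirror_knee_model(model)
    poses <- mirror_poses(poses)
  }
  frames <- frames %||% knee_reference_frames(model, resection)
  fem_body <- if (model$type == "tka") "femoral_component" else "femur"
  tib_body <- if (model$type == "tka") "baseplate" else "tibia"
  idx <- sort(unique(poses$frame_index))
  rel <- lapply(idx, function(fi)
    invert_transform(pose_matrix(poses, fi, tib_body)) %*%
      pose_matrix(poses, fi, fem_body))
  stored <- vapply(idx, function(fi)
    poses$flexion_deg[which(poses$frame_index == fi &
                              poses$body == fem_body)[1L]], numeric(1L))
  flex <- frame_flexion(model, rel, stored)
  pos <- do.call(rbind, lapply(rel, function(M)
    condylar_positions(model, M, frames$frame, frames$reference)))
  sel <- match_schedule(flex, schedule)
  track_df <- do.call(rbind, lapply(seq_along(schedule), function(s) {
    m <- sel[[s]]
    row <- m$w * pos[m$i, ] + (1 - m$w) * pos[m$j, ]
    cbind(flexion_deg = schedule[s], row)
  }))
  ref_kind <- if (model$type == "tka") "tka_baseplate_bbox" else "native_resection_plane"
  track <- condylar_track(track_df, reference = ref_kind, activity = activity)
  profile <- build_rotation_profile(track, activity, schedule)
  std <- standardize_ap(track, standardization_params(50, frames$frame$ap_extent))
  list(track = track, track_std = std, profile = profile, frames = frames)
}

#' Analyze a knee with repeated registrations
#'
#' Applies independent registration noise `repeats` times (seeds derived
#' from `noise$seed`), analyzes each noisy pose sequence, and averages the
#' condylar tracks before deriving the rotation profile - the three-repeat
#' averaging used for bone-model registration.
#'
#' @param model a `knee_model`.
#' @param poses the noise-free [pose_sequence()].
#' @param noise a [noise_spec()].
#' @param repeats number of registration repeats (default 3).
#' @param frames optional precomputed [knee_reference_frames()].
#' @param ... passed to [analyze_knee()].
#' @return As [analyze_knee()], with `track` the repeat-averaged track.
#' @export
analyze_with_repeats <- function(model, poses, noise = noise_spec(),
                                 repeats = 3L, frames = NULL, ...) {
  frames <- frames %||% knee_reference_frames(model)
  tracks <- lapply(seq_len(repeats), function(r) {
    ns <- noise
    ns$seed <- noise$seed + (r - 1L) * 10007L
    noisy <- apply_registration_noise(poses, ns)
    analyze_knee(model, noisy, frames = frames, ...)$track
  })
  track <- average_repeats(tracks)
  activity <- attr(track, "activity")
  profile <- build_rotation_profile(track, activity)
  std <- standardize_ap(track, standardization_params(50, frames$frame$ap_extent))
  list(track = track, track_std = std, profile = profile, frames = frames)
}

## ---- run_* entry points (library surface of the CLI) -----------------------

#' Simulate a knee dataset on disk
#'
#' Generates a model and ground-truth trajectory, optionally applies
#' registration noise, and writes meshes (STL), the pose CSV and the
#' ground-truth sidecar into `dir`. Identical config and seed give
#' identical outputs.
#'
#' @param dir output directory.
#' @param type `"native"` or `"tka"`.
#' @param activity `"step_up"` or `"chair_rise"`.
#' @param spec a [knee_spec()] / [tka_spec()]; defaults per `type`.
#' @param motion a [motion_spec()]; default screw-home for native,
#'   progressive for TKA.
#' @param noise optional [noise_spec()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(dir, type = c("native", "tka"),
                         activity = c("step_up", "chair_rise"),
                         spec = NULL, motion = NULL, noise = NULL) {
  type <- match.arg(type)
  activity <- match.arg(activity)
  model <- if (type == "tka") generate_tka_model(spec %||% tka_spec())
  else generate_knee_model(spec %||% knee_spec())
  motion <- motion %||% motion_spec(
    activity = activity,
    rotation_path = if (type == "tka") "progressive" else "screw_home")
  traj <- generate_trajectory(model, motion)
  if (!is.null(noise)) traj$poses <- apply_registration_noise(traj$poses, noise)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_knee_model(model, dir)
  write_poses(traj$poses, file.path(dir, "poses.csv"))
  write_ground_truth(traj$truth, file.path(dir, "ground_truth.csv"))
  invisible(list(dir = dir,
                 poses = file.path(dir, "poses.csv"),
                 ground_truth = file.path(dir, "ground_truth.csv")))
}

#' Analyze a simulated or imported knee dataset on disk
#'
#' Reads the model and poses from `dir` (as written by [run_simulate()]),
#' runs [analyze_knee()], and writes the track and profile CSVs plus a JSON
#' frame report (tibial frame origin and axes, varus-valgus adjustment,
#' A-P dimension).
#'
#' @param dir dataset directory.
#' @param activity `"step_up"` or `"chair_rise"`.
#' @param out output directory (default `dir`).
#' @return Invisibly, the [analyze_knee()] result.
#' @export
run_analyze <- function(dir, activity = c("step_up", "chair_rise"), out = dir) {
  activity <- match.arg(activity)
  model <- read_knee_model(dir)
  poses <- read_poses(file.path(dir, "poses.csv"))
  res <- analyze_knee(model, poses, activity)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_track(res$track, file.path(out, "track.csv"))
  write_track(res$track_std, file.path(out, "track_standardized.csv"))
  write_profile(res$profile, file.path(out, "profile.csv"))
  fr <- res$frames
  report <- list(origin = fr$frame$origin,
                 ml = fr$frame$ml, ap = fr$frame$ap, pd = fr$frame$pd,
                 ap_dimension_mm = fr$frame$ap_extent,
                 vv_applied_deg = if (!is.null(fr$resection)) fr$resection$vv_applied else 0,
                 max_flexion_rotation_deg = res$profile$max_flexion_rotation)
  jsonlite::write_json(report, file.path(out, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Compare two groups of profile files
#'
#' @param paths_a,paths_b character vectors of profile CSV paths (groups A
#'   and B).
#' @param out optional JSON report path.
#' @return The [compare_groups()] data frame, invisibly if `out` is given.
#' @export
run_stats <- function(paths_a, paths_b, out = NULL) {
  pa <- lapply(paths_a, read_profile)
  pb <- lapply(paths_b, read_profile)
  res <- compare_groups(pa, pb)
  if (!is.null(out)) {
    jsonlite::write_json(res, out, dataframe = "rows", digits = NA)
    return(invisible(res))
  }
  res
}

#' Run the power / minimum-detectable-difference analysis
#'
#' @param spec a [power_spec()].
#' @param delta optional true difference (deg) at which to also report
#'   power.
#' @return List with `spec`, `detectable_difference` and (when `delta` is
#'   given) `power_at_delta`.
#' @export
run_power <- function(spec = power_spec(), delta = NULL) {
  out <- list(spec = unclass(spec),
              detectable_difference = detectable_difference(spec))
  if (!is.null(delta)) out$power_at_delta <- power_at(delta, spec)
  out
}
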