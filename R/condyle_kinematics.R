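# Lowest-point condylar tracking: per-frame medial/lateral condylar
# positions relative to the tibial reference, repeat averaging, A-P
# standardization, and internal-external rotation profiles.

#' A-P standardization parameters
#'
#' A-P positions are scaled by `reference_ap_depth / subject_ap_depth` so
#' that knees of different sizes are compared on a common 50 mm reference
#' plateau depth. Standardized tracks are flagged and may not be used for
#' rotation (rotation is defined on the non-standardized positions).
#'
#' @param reference_ap_depth reference plateau/baseplate A-P depth (mm).
#' @param subject_ap_depth this knee's plateau or baseplate A-P depth (mm).
#' @return A validated list of class `standardization_params`.
#' @export
standardization_params <- function(reference_ap_depth = 50, subject_ap_depth) {
  stopifnot_scalar_number(reference_ap_depth, "reference_ap_depth", positive = TRUE)
  stopifnot_scalar_number(subject_ap_depth, "subject_ap_depth", positive = TRUE)
  structure(list(reference_ap_depth = reference_ap_depth,
                 subject_ap_depth = subject_ap_depth),
            class = "standardization_params")
}

#' Lowest point of a posed surface with respect to a reference plane
#'
#' Transforms the mesh vertices by the pose and returns the vertex
#' minimizing signed distance to the reference plane. Vertices within
#' `tie_tol` of the minimum are tied and resolved by the centroid of the
#' tied set, which makes the result robust to mesh jitter on near-flat
#' regions.
#'
#' @param mesh a [surface_mesh()] (or an n x 3 vertex matrix).
#' @param pose 4x4 rigid transform of the body.
#' @param reference a [plane()] whose normal points away from the surface
#'   (proximally for a tibial reference).
#' @param tie_tol tie tolerance (mm, default 0.05).
#' @return Length-3 point (mm) with attribute `n_tied`.
#' @export
lowest_point <- function(mesh, pose = diag(4), reference, tie_tol = 0.05) {
  verts <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  if (!nrow(verts)) kt_parameter_error("empty mesh in lowest_point()")
  msg <- check_rotation(pose[1:3, 1:3])
  if (!is.null(msg)) kt_parameter_error(paste("invalid pose:", msg))
  pv <- transform_points(pose, verts)
  d <- plane_distance(reference, pv)
  tied <- which(d <= min(d) + tie_tol)
  p <- colMeans(pv[tied, , drop = FALSE])
  attr(p, "n_tied") <- length(tied)
  p
}

#' Condylar (A-P, M-L) positions in a tibial reference frame
#'
#' Computes the lowest point of each femoral condylar patch under the given
#' femur-relative-to-tibia pose, and expresses it as (A-P, M-L) coordinates
#' in the supplied frame (A-P positive anterior, M-L positive lateral).
#'
#' @param model a `knee_model` or `tka_model` whose femoral body carries
#'   `condyle_medial` / `condyle_lateral` labels.
#' @param pose 4x4 rigid transform of the femoral body relative to the
#'   tibial body.
#' @param frame a `tibial_frame` (native resection frame or
#'   [baseplate_frame()]).
#' @param reference the lowest-point reference [plane()]; defaults to the
#'   frame's `reference_plane` or, failing that, the plane through the frame
#'   origin normal to its proximal axis.
#' @return One-row data frame with `ap_med`, `ml_med`, `ap_lat`, `ml_lat`
#'   (mm).
#' @export
condylar_positions <- function(model, pose = diag(4), frame, reference = NULL) {
  reference <- reference %||% frame$reference_plane %||%
    plane(frame$origin, frame$pd)
  coords <- function(p) {
    rel <- p - frame$origin
    c(ap = sum(rel * frame$ap), ml = sum(rel * frame$ml))
  }
  med <- coords(lowest_point(mesh_patch(model$femur, "condyle_medial"),
                             pose, reference))
  lat <- coords(lowest_point(mesh_patch(model$femur, "condyle_lateral"),
                             pose, reference))
  data.frame(ap_med = med[["ap"]], ml_med = med[["ml"]],
             ap_lat = lat[["ap"]], ml_lat = lat[["ml"]])
}

#' Condylar track container
#'
#' One row per schedule flexion angle with the medial and lateral condylar
#' (A-P, M-L) positions in the tibial frame.
#'
#' @param df data frame with columns `flexion_deg`, `ap_med`, `ml_med`,
#'   `ap_lat`, `ml_lat` (mm).
#' @param reference `"native_resection_plane"` or `"tka_baseplate_bbox"`.
#' @param activity activity name (optional annotation).
#' @param repeats number of registration repeats averaged into the track.
#' @param standardized whether A-P columns have been standardized.
#' @return The data frame with class `condylar_track` and the metadata as
#'   attributes.
#' @export
condylar_track <- function(df, reference = c("native_resection_plane",
                                             "tka_baseplate_bbox"),
                           activity = NA_character_, repeats = 1L,
                           standardized = FALSE) {
  reference <- match.arg(reference)
  need <- c("flexion_deg", "ap_med", "ml_med", "ap_lat", "ml_lat")
  if (!all(need %in% names(df)))
    kt_parameter_error(paste("track needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$flexion_deg))
    kt_parameter_error("one record per schedule flexion angle is required")
  df <- as.data.frame(df)[need]
  df <- df[order(-df$flexion_deg), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("condylar_track", "data.frame"),
            reference = reference, activity = activity,
            repeats = as.integer(repeats), standardized = isTRUE(standardized))
}

track_meta <- function(track)
  attributes(track)[c("reference", "activity", "repeats", "standardized")]

#' Average repeated registrations of a track
#'
#' Coordinate-wise arithmetic mean of tracks sharing the same schedule and
#' reference (the three-repeat averaging applied to bone-model
#' registrations).
#'
#' @param tracks list of [condylar_track()]s.
#' @return A [condylar_track()] with `repeats` set to the number averaged.
#' @export
average_repeats <- function(tracks) {
  if (inherits(tracks, "condylar_track")) tracks <- list(tracks)
  if (!length(tracks)) kt_parameter_error("no tracks to average")
  sched <- tracks[[1L]]$flexion_deg
  ref <- attr(tracks[[1L]], "reference")
  for (tr in tracks) {
    if (!isTRUE(all.equal(tr$flexion_deg, sched)))
      kt_parameter_error("tracks have mismatched flexion schedules")
    if (!identical(attr(tr, "reference"), ref))
      kt_parameter_error("tracks have mismatched reference kinds")
    if (isTRUE(attr(tr, "standardized")))
      kt_contract_error("standardized tracks cannot be averaged as repeats")
  }
  out <- tracks[[1L]]
  for (col in c("ap_med", "ml_med", "ap_lat", "ml_lat"))
    out[[col]] <- rowMeans(vapply(tracks, function(tr) tr[[col]],
                                  numeric(length(sched))))
  condylar_track(out, reference = ref, activity = attr(tracks[[1L]], "activity"),
                 repeats = length(tracks), standardized = FALSE)
}

#' Standardize A-P positions to the reference plateau depth
#'
#' Multiplies the A-P coordinates by `reference_ap_depth / subject_ap_depth`
#' (M-L unchanged) and flags the track as standardized; standardized tracks
#' are rejected by [ie_rotation()] since rotation is defined on the
#' non-standardized positions.
#'
#' @param track a [condylar_track()].
#' @param params a [standardization_params()].
#' @return The standardized [condylar_track()].
#' @export
standardize_ap <- function(track, params) {
  if (!inherits(params, "standardization_params"))
    params <- do.call(standardization_params, params)
  ratio <- params$reference_ap_depth / params$subject_ap_depth
  out <- track
  out$ap_med <- track$ap_med * ratio
  out$ap_lat <- track$ap_lat * ratio
  condylar_track(out, reference = attr(track, "reference"),
                 activity = attr(track, "activity"),
                 repeats = attr(track, "repeats"), standardized = TRUE)
}

# Orientation (deg) of the medial-lateral line through the condylar
# positions at flexion angle f, measured in the tibial frame.
track_theta <- function(track, f) {
  i <- match(f, track$flexion_deg)
  if (is.na(i))
    kt_parameter_error(sprintf("flexion angle %g deg is not in the track schedule", f))
  rad2deg(atan2(track$ap_med[i] - track$ap_lat[i],
                track$ml_lat[i] - track$ml_med[i]))
}

#' Internal-external rotation between two flexion angles
#'
#' The angle between the medial-lateral lines connecting the
#' (non-standardized) medial and lateral condylar positions at the two
#' flexion angles: `theta(f) = atan2(ap_med - ap_lat, ml_lat - ml_med)`,
#' returned as `theta(flex_a) - theta(flex_b)`. Positive values are internal
#' tibial rotation (lateral femoral condyle posterior relative to the
#' medial) in the right-knee convention.
#'
#' @param track a non-standardized [condylar_track()].
#' @param flex_a,flex_b flexion angles present in the track (deg).
#' @return Rotation in degrees.
#' @export
ie_rotation <- function(track, flex_a, flex_b) {
  if (isTRUE(attr(track, "standardized")))
    kt_contract_error("rotation must be computed from a non-standardized track")
  track_theta(track, flex_a) - track_theta(track, flex_b)
}

#' Rotation profile and arcs of extension
#'
#' Computes the internal-external rotation at every schedule angle relative
#' to full extension, the per-arc rotation changes (15 deg arcs for step up:
#' 60-45, 45-30, 30-15, 15-0; 30 deg arcs for chair rise: 90-60, 60-30,
#' 30-0), and the rotation at maximum flexion (which the arc deltas
#' telescope to exactly).
#'
#' @param track a non-standardized [condylar_track()] covering the activity
#'   schedule.
#' @param activity `"step_up"` or `"chair_rise"`.
#' @param schedule optional schedule override (deg, strictly decreasing,
#'   ending at 0).
#' @return An object of class `rotation_profile`: `activity`, `schedule`,
#'   `rotation` (data frame `flexion_deg`, `rotation_deg`), `arcs` (data
#'   frame `arc`, `flex_from`, `flex_to`, `delta_deg`) and
#'   `max_flexion_rotation` (deg).
#' @export
build_rotation_profile <- function(track, activity = c("step_up", "chair_rise"),
                                   schedule = NULL) {
  activity <- match.arg(activity)
  schedule <- schedule %||% activity_schedule(activity)
  missing_angles <- setdiff(schedule, track$flexion_deg)
  if (length(missing_angles))
    kt_parameter_error(paste("track is missing schedule angles:",
                             paste(missing_angles, collapse = ", ")))
  theta <- vapply(schedule, function(f) track_theta(track, f), numeric(1L))
  theta0 <- theta[length(theta)]               # extension reference
  rotation <- data.frame(flexion_deg = schedule, rotation_deg = theta - theta0)
  n <- length(schedule)
  arcs <- data.frame(
    arc = sprintf("%g-%g", schedule[-n], schedule[-1L]),
    flex_from = schedule[-n], flex_to = schedule[-1L],
    delta_deg = theta[-n] - theta[-1L])
  structure(list(activity = activity, schedule = schedule,
                 rotation = rotation, arcs = arcs,
                 max_flexion_rotation = theta[1L] - theta0),
            class = "rotation_profile")
}

#' @export
print.rotation_profile <- function(x, ...) {
  cat(sprintf("<rotation_profile> %s, rotation at maximum flexion %.2f deg\n",
              x$activity, x$max_flexion_rotation))
  print(x$rotation, row.names = FALSE)
  cat("arcs of extension:\n")
  print(x$arcs, row.names = FALSE)
  invisible(x)
}
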