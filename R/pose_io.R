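# Pose sequences: per-frame rigid transforms of the femoral and tibial
# bodies, stored tidily (one body-frame observation per row) with the
# row-major rotation entries r11..r33 and translation tx,ty,tz in mm.
# Transforms map body-local mm coordinates into the lab frame.

POSE_BODIES <- c("femur", "tibia", "femoral_component", "baseplate")
POSE_COLS <- c("frame_index", "body",
               "r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33",
               "tx", "ty", "tz", "flexion_deg")

pose_row <- function(frame_index, body, T, flexion_deg = NA_real_) {
  R <- T[1:3, 1:3]
  data.frame(frame_index = as.integer(frame_index), body = body,
             r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
             r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
             r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
             tx = T[1, 4], ty = T[2, 4], tz = T[3, 4],
             flexion_deg = flexion_deg, stringsAsFactors = FALSE)
}

pose_matrix_row <- function(row) {
  R <- matrix(as.numeric(row[c("r11", "r12", "r13", "r21", "r22", "r23",
                               "r31", "r32", "r33")]), 3L, 3L, byrow = TRUE)
  rigid_transform(R, as.numeric(row[c("tx", "ty", "tz")]))
}

#' Pose sequence container
#'
#' Validates and orders a data frame of per-frame rigid poses. Rotations
#' must be orthonormal within 1e-6 with determinant +1 (reflections are
#' rejected); rows are sorted by frame index then body.
#'
#' @param df data frame with columns `frame_index`, `body`, `r11`..`r33`
#'   (row-major rotation), `tx`, `ty`, `tz` (mm) and optionally
#'   `flexion_deg`.
#' @return The validated data frame with class `pose_sequence`.
#' @export
pose_sequence <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$flexion_deg)) df$flexion_deg <- NA_real_
  missing_cols <- setdiff(POSE_COLS, names(df))
  if (length(missing_cols))
    kt_format_error(paste("pose table is missing columns:",
                          paste(missing_cols, collapse = ", ")))
  df <- df[POSE_COLS]
  bad <- !df$body %in% POSE_BODIES
  if (any(bad))
    kt_format_error(paste("unknown body name(s):",
                          paste(unique(df$body[bad]), collapse = ", ")))
  for (i in seq_len(nrow(df))) {
    R <- matrix(as.numeric(df[i, c("r11", "r12", "r13", "r21", "r22", "r23",
                                   "r31", "r32", "r33")]), 3L, 3L, byrow = TRUE)
    msg <- check_rotation(R)
    if (!is.null(msg))
      kt_format_error(sprintf("invalid rotation at frame %d body '%s': %s",
                              df$frame_index[i], df$body[i], msg))
  }
  df <- df[order(df$frame_index, df$body), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pose_sequence", "data.frame")
  df
}

#' Extract one 4x4 pose from a sequence
#'
#' @param poses a [pose_sequence()].
#' @param frame frame index.
#' @param body body name.
#' @return A 4x4 rigid transform.
#' @export
pose_matrix <- function(poses, frame, body) {
  i <- which(poses$frame_index == frame & poses$body == body)
  if (length(i) != 1L)
    kt_parameter_error(sprintf("no unique pose for frame %s body '%s'", frame, body))
  pose_matrix_row(poses[i, ])
}

#' Read / write pose sequences as CSV
#'
#' The CSV has one row per (frame, body) with a header; see
#' [pose_sequence()] for the columns. Reading validates every rotation and
#' sorts frames; a write-read round trip is stable.
#'
#' @param path file path.
#' @return `read_poses()` returns a [pose_sequence()];
#'   `write_poses()` returns `path` invisibly.
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) kt_format_error(paste("no such pose file:", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) kt_format_error(
                   sprintf("cannot parse pose CSV '%s': %s", path, conditionMessage(e))))
  pose_sequence(df)
}

#' @rdname read_poses
#' @param poses a [pose_sequence()].
#' @export
write_poses <- function(poses, path) {
  stopifnot(inherits(poses, "pose_sequence"))
  utils::write.csv(as.data.frame(poses), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mirror a pose sequence across the sagittal plane
#'
#' Conjugates every pose with the mirror that negates the medial-lateral
#' axis, so mirrored poses applied to mirrored meshes reproduce the mirrored
#' motion. Used to bring left-knee data into the right-knee convention.
#'
#' @param poses a [pose_sequence()].
#' @return The mirrored [pose_sequence()].
#' @export
mirror_poses <- function(poses) {
  S <- diag(c(1, -1, 1, 1))
  out <- lapply(seq_len(nrow(poses)), function(i) {
    M <- S %*% pose_matrix_row(poses[i, ]) %*% S
    pose_row(poses$frame_index[i], poses$body[i], M, poses$flexion_deg[i])
  })
  pose_sequence(do.call(rbind, out))
}

## ---- ground truth sidecar --------------------------------------------------

#' Read / write the ground-truth sidecar CSV
#'
#' Columns: `frame`, `flexion_deg`, `true_ie_deg`, `true_ap_med_mm`,
#' `true_ap_lat_mm`.
#'
#' @param truth ground-truth data frame (from [generate_trajectory()]).
#' @param path file path.
#' @return `read_ground_truth()` returns the data frame;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) kt_format_error(paste("no such file:", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
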