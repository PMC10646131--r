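# Parametric synthetic knee / TKA geometry and ground-truth trajectories.
#
# Model coordinates (right-knee convention, extension pose):
#   x = +anterior, y = +medial, z = +proximal, origin at the center of the
#   tibial plateau on the medial articular surface (joint line, z = 0).
# Femoral condyles are spheres of the given radii tangent to z = 0 from
# above; the tibial medial articular surface is the plane z = 0. Every
# downstream quantity (lowest points, thicknesses, rotations) therefore has
# a closed form, recorded in the model's `landmarks` for oracle testing.

#' Synthetic native-knee geometry specification
#'
#' @param side `"right"` or `"left"`. Left knees are generated by mirroring
#'   the right-knee model across the sagittal plane.
#' @param medial_condyle_radius,lateral_condyle_radius femoral condylar
#'   sphere radii (mm).
#' @param condyle_ml_separation center-to-center medial-lateral distance
#'   between the condylar spheres (mm).
#' @param plateau_ap_depth,plateau_ml_width tibial plateau extents (mm).
#' @param plateau_varus_angle frontal-plane tilt of the lateral articular
#'   surface relative to the medial one (deg); 0 = coplanar.
#' @param shaft_length_femur,shaft_length_tibia bone shaft lengths (mm),
#'   at least 130 so the 12 cm anatomic-axis level lies within the bone.
#' @param condyle_edge_mm target mesh edge length on the condylar spheres
#'   (mm). Finer than the rest of the bone so the lowest-point tie-centroid
#'   resolves sphere tangency to better than 0.1 mm.
#' @param mesh_edge_mm target mesh edge length for plateau and shafts (mm).
#' @return A validated list of class `knee_spec`.
#' @export
knee_spec <- function(side = c("right", "left"),
                      medial_condyle_radius = 22,
                      lateral_condyle_radius = 22,
                      condyle_ml_separation = 46,
                      plateau_ap_depth = 50,
                      plateau_ml_width = 76,
                      plateau_varus_angle = 0,
                      shaft_length_femur = 150,
                      shaft_length_tibia = 150,
                      condyle_edge_mm = 0.3,
                      mesh_edge_mm = 1) {
  side <- match.arg(side)
  stopifnot_scalar_number(medial_condyle_radius, "medial_condyle_radius", positive = TRUE)
  stopifnot_scalar_number(lateral_condyle_radius, "lateral_condyle_radius", positive = TRUE)
  stopifnot_scalar_number(condyle_ml_separation, "condyle_ml_separation", positive = TRUE)
  stopifnot_scalar_number(plateau_ap_depth, "plateau_ap_depth", positive = TRUE)
  stopifnot_scalar_number(plateau_ml_width, "plateau_ml_width", positive = TRUE)
  stopifnot_scalar_number(plateau_varus_angle, "plateau_varus_angle")
  stopifnot_scalar_number(condyle_edge_mm, "condyle_edge_mm", positive = TRUE)
  stopifnot_scalar_number(mesh_edge_mm, "mesh_edge_mm", positive = TRUE)
  for (nm in c("shaft_length_femur", "shaft_length_tibia")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm, positive = TRUE)
    if (v < 130)
      kt_parameter_error(sprintf(
        "'%s' must be >= 130 mm so the 120 mm axis level lies within the bone (got %g)",
        nm, v))
  }
  structure(mget(c("side", "medial_condyle_radius", "lateral_condyle_radius",
                   "condyle_ml_separation", "plateau_ap_depth", "plateau_ml_width",
                   "plateau_varus_angle", "shaft_length_femur", "shaft_length_tibia",
                   "condyle_edge_mm", "mesh_edge_mm")),
            class = "knee_spec")
}

#' Synthetic TKA component specification
#'
#' Extends [knee_spec()] with the implant parameters: a constant-radius
#' femoral component (both condylar surfaces use `medial_condyle_radius`)
#' and a rectangular tibial baseplate.
#'
#' @param baseplate_ap_depth anterior-posterior extent of the baseplate (mm);
#'   50 mm is the mid-sized reference.
#' @param baseplate_ml_width medial-lateral extent of the baseplate (mm).
#' @param insert_type insert articular geometry; the supported design is a
#'   fully conforming medial compartment with a flat lateral surface, which
#'   pins medial A-P translation (medial pivot).
#' @param ... passed to [knee_spec()].
#' @return A validated list of class `c("tka_spec", "knee_spec")`.
#' @export
tka_spec <- function(baseplate_ap_depth = 50,
                     baseplate_ml_width = 70,
                     insert_type = "ball_in_socket_medial_flat_lateral",
                     ...) {
  stopifnot_scalar_number(baseplate_ap_depth, "baseplate_ap_depth", positive = TRUE)
  stopifnot_scalar_number(baseplate_ml_width, "baseplate_ml_width", positive = TRUE)
  insert_type <- match.arg(insert_type, "ball_in_socket_medial_flat_lateral")
  base <- knee_spec(...)
  spec <- c(base, list(baseplate_ap_depth = baseplate_ap_depth,
                       baseplate_ml_width = baseplate_ml_width,
                       insert_type = insert_type))
  # constant-radius femoral component
  spec$lateral_condyle_radius <- spec$medial_condyle_radius
  structure(spec, class = c("tka_spec", "knee_spec"))
}

#' Synthetic motion specification
#'
#' Defines the activity, the flexion schedule, and the internal-external
#' rotation path the generator imposes. Rotation is expressed relative to
#' full extension (0 deg flexion), internal positive.
#'
#' @param activity `"step_up"` or `"chair_rise"`.
#' @param flexion_schedule strictly decreasing flexion angles (deg);
#'   defaults to 60,45,30,15,0 for step up and 90,60,30,0 for chair rise.
#' @param rotation_path `"screw_home"` (native pattern: most rotation in the
#'   terminal extension arc) or `"progressive"` (rotation linear in flexion,
#'   the medial-pivot TKA pattern).
#' @param max_internal_rotation internal tibial rotation at maximum flexion
#'   (deg).
#' @param medial_posterior_shift_at_30 posterior shift of the medial femoral
#'   condyle at 30 deg flexion relative to extension (mm). `NULL` resolves to
#'   5.1 (step up) / 4.5 (chair rise) for the screw-home path and 0 for the
#'   progressive (medial-pivot) path.
#' @param terminal_fraction fraction of the total rotation accrued in the
#'   final schedule arc under the screw-home path (default 0.7).
#' @param frames_per_arc pose frames generated per schedule arc.
#' @return A validated list of class `motion_spec`.
#' @export
motion_spec <- function(activity = c("step_up", "chair_rise"),
                        flexion_schedule = NULL,
                        rotation_path = c("screw_home", "progressive"),
                        max_internal_rotation = 13,
                        medial_posterior_shift_at_30 = NULL,
                        terminal_fraction = 0.7,
                        frames_per_arc = 1L) {
  activity <- match.arg(activity)
  rotation_path <- match.arg(rotation_path)
  if (is.null(flexion_schedule)) flexion_schedule <- activity_schedule(activity)
  flexion_schedule <- as.numeric(flexion_schedule)
  if (length(flexion_schedule) < 2L || any(diff(flexion_schedule) >= 0))
    kt_parameter_error("'flexion_schedule' must be strictly decreasing with >= 2 angles")
  if (any(flexion_schedule < 0 | flexion_schedule > 150))
    kt_parameter_error("schedule angles must lie in [0, 150] deg")
  stopifnot_scalar_number(max_internal_rotation, "max_internal_rotation")
  if (is.null(medial_posterior_shift_at_30)) {
    medial_posterior_shift_at_30 <- if (rotation_path == "screw_home") {
      if (activity == "step_up") 5.1 else 4.5
    } else 0
  }
  stopifnot_scalar_number(medial_posterior_shift_at_30,
                          "medial_posterior_shift_at_30", nonneg = TRUE)
  stopifnot_scalar_number(terminal_fraction, "terminal_fraction")
  if (terminal_fraction <= 0 || terminal_fraction >= 1)
    kt_parameter_error("'terminal_fraction' must be in (0, 1)")
  frames_per_arc <- as.integer(frames_per_arc)
  if (frames_per_arc < 1L) kt_parameter_error("'frames_per_arc' must be >= 1")
  structure(list(activity = activity, flexion_schedule = flexion_schedule,
                 rotation_path = rotation_path,
                 max_internal_rotation = max_internal_rotation,
                 medial_posterior_shift_at_30 = medial_posterior_shift_at_30,
                 terminal_fraction = terminal_fraction,
                 frames_per_arc = frames_per_arc),
            class = "motion_spec")
}

#' Flexion schedule of an activity
#'
#' @param activity `"step_up"` or `"chair_rise"`.
#' @return Numeric vector of flexion angles (deg), decreasing to 0.
#' @export
activity_schedule <- function(activity = c("step_up", "chair_rise")) {
  switch(match.arg(activity),
         step_up = c(60, 45, 30, 15, 0),
         chair_rise = c(90, 60, 30, 0))
}

#' Registration-noise specification
#'
#' Stand-in for single-plane fluoroscopic registration imprecision: the
#' image plane is the (anterior, proximal) plane, so translation noise is
#' anisotropic with a larger out-of-plane (medial-lateral) sigma. Rotation
#' noise is a rotation vector with independent zero-mean components.
#'
#' @param sigma_translation_inplane SD of in-plane (A-P, P-D) translation
#'   noise (mm).
#' @param sigma_translation_outofplane SD of out-of-plane (M-L) translation
#'   noise (mm).
#' @param sigma_rotation per-axis SD of the rotation-vector noise (deg).
#' @param seed integer RNG seed (mandatory: noisy stages must be reproducible).
#' @return A validated list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_translation_inplane = 0.25,
                       sigma_translation_outofplane = 2,
                       sigma_rotation = 0.5,
                       seed = 1L) {
  stopifnot_scalar_number(sigma_translation_inplane, "sigma_translation_inplane", nonneg = TRUE)
  stopifnot_scalar_number(sigma_translation_outofplane, "sigma_translation_outofplane", nonneg = TRUE)
  stopifnot_scalar_number(sigma_rotation, "sigma_rotation", nonneg = TRUE)
  stopifnot_scalar_number(seed, "seed")
  structure(list(sigma_translation_inplane = sigma_translation_inplane,
                 sigma_translation_outofplane = sigma_translation_outofplane,
                 sigma_rotation = sigma_rotation, seed = as.integer(seed)),
            class = "noise_spec")
}

## ---- model generation ------------------------------------------------------

SHAFT_RADIUS <- 14

#' Generate a synthetic native knee model
#'
#' Builds watertight femur and tibia meshes from a [knee_spec()] together
#' with the analytic landmark record (condylar sphere centers and radii,
#' articular plateau planes, joint line, shaft axes) that downstream
#' operations and oracle tests rely on.
#'
#' @param spec a [knee_spec()].
#' @return An object of class `knee_model` with elements `femur`, `tibia`
#'   (both [surface_mesh()]), `landmarks`, `spec` and `type = "native"`.
#' @export
generate_knee_model <- function(spec = knee_spec()) {
  if (!inherits(spec, "knee_spec")) spec <- do.call(knee_spec, spec)
  sep <- spec$condyle_ml_separation
  rm_ <- spec$medial_condyle_radius
  rl_ <- spec$lateral_condyle_radius
  half <- sep / 2

  femur <- build_femur(rm_, rl_, half, spec$shaft_length_femur, spec$condyle_edge_mm)
  tibia <- build_tibia(spec, half)

  varus <- deg2rad(spec$plateau_varus_angle)
  landmarks <- list(
    condyle_center_medial = c(0, half, rm_),
    condyle_center_lateral = c(0, -half, rl_),
    condyle_radius_medial = rm_,
    condyle_radius_lateral = rl_,
    condyle_ml_separation = sep,
    joint_line_femur = 0,
    joint_line_tibia = 0,
    femur_shaft_axis = list(point = c(0, 0, 0), dir = c(0, 0, 1)),
    tibia_shaft_axis = list(point = c(0, 0, 0), dir = c(0, 0, -1)),
    plateau_plane_medial = plane(c(0, half, 0), c(0, 0, 1)),
    plateau_plane_lateral = plane(c(0, -half, tan(varus) * half),
                                  c(0, sin(varus), cos(varus))),
    tibial_condyle_center_medial = c(0, half, 0),
    tibial_condyle_center_lateral = c(0, -half, tan(varus) * half),
    plateau_ap_depth = spec$plateau_ap_depth,
    plateau_ml_width = spec$plateau_ml_width)

  model <- structure(list(femur = femur, tibia = tibia,
                          landmarks = landmarks, spec = spec, type = "native"),
                     class = "knee_model")
  if (spec$side == "left") model <- mirror_knee_model(model)
  model
}

build_femur <- function(rm_, rl_, half, shaft_len, condyle_edge) {
  med <- icosphere(rm_, center = c(0, half, rm_), edge = condyle_edge)
  lat <- icosphere(rl_, center = c(0, -half, rl_), edge = condyle_edge)
  med$labels <- list(condyle_medial = seq_len(nrow(med$vertices)))
  lat$labels <- list(condyle_lateral = seq_len(nrow(lat$vertices)))
  rmax <- max(rm_, rl_)
  meta <- box_mesh(center = c(0, 0, rmax + 15), dims = c(1.2 * rmax, 2 * half + 10, 50))
  meta$labels <- list(metaphysis = seq_len(nrow(meta$vertices)))
  shaft <- cylinder_mesh(SHAFT_RADIUS, z_from = rmax + 15, z_to = shaft_len, n_seg = 64L)
  shaft$labels <- list(shaft = seq_len(nrow(shaft$vertices)))
  merge_meshes(med, lat, meta, shaft)
}

build_tibia <- function(spec, half) {
  varus <- deg2rad(spec$plateau_varus_angle)
  ztop <- function(x, y) ifelse(y >= 0, 0, -y * tan(varus))
  slab <- slab_mesh(c(-spec$plateau_ap_depth / 2, spec$plateau_ap_depth / 2),
                    c(-spec$plateau_ml_width / 2, spec$plateau_ml_width / 2),
                    z_bottom = -30, z_top_fun = ztop, edge = spec$mesh_edge_mm)
  top_idx <- slab$labels$top
  tv <- slab$vertices[top_idx, , drop = FALSE]
  patch_r <- min(12, half - 1)
  med_patch <- top_idx[sqrt(tv[, 1L]^2 + (tv[, 2L] - half)^2) <= patch_r]
  lat_patch <- top_idx[sqrt(tv[, 1L]^2 + (tv[, 2L] + half)^2) <= patch_r]
  slab$labels <- list(plateau_top = top_idx,
                      plateau_medial = med_patch,
                      plateau_lateral = lat_patch)
  shaft <- cylinder_mesh(SHAFT_RADIUS, z_from = -spec$shaft_length_tibia,
                         z_to = -25, n_seg = 64L)
  shaft$labels <- list(shaft = seq_len(nrow(shaft$vertices)))
  merge_meshes(slab, shaft)
}

#' Generate a synthetic TKA model
#'
#' Builds the femoral component (constant-radius condylar spheres) and a
#' rectangular tibial baseplate whose bounding box has exactly the specified
#' A-P depth. The baseplate top surface lies at the joint line (z = 0) and is
#' the lowest-point reference plane for TKA tracks.
#'
#' @param spec a [tka_spec()].
#' @return An object of class `c("tka_model", "knee_model")` with elements
#'   `femur` (the femoral component), `baseplate`, `landmarks`, `spec`,
#'   `type = "tka"`.
#' @export
generate_tka_model <- function(spec = tka_spec()) {
  if (!inherits(spec, "tka_spec")) spec <- do.call(tka_spec, spec)
  r <- spec$medial_condyle_radius
  half <- spec$condyle_ml_separation / 2
  med <- icosphere(r, center = c(0, half, r), edge = spec$condyle_edge_mm)
  lat <- icosphere(r, center = c(0, -half, r), edge = spec$condyle_edge_mm)
  med$labels <- list(condyle_medial = seq_len(nrow(med$vertices)))
  lat$labels <- list(condyle_lateral = seq_len(nrow(lat$vertices)))
  bridge <- box_mesh(center = c(0, 0, r + 8), dims = c(0.8 * r, 2 * half, 16))
  comp <- merge_meshes(med, lat, bridge)
  plate <- box_mesh(center = c(0, 0, -5),
                    dims = c(spec$baseplate_ap_depth, spec$baseplate_ml_width, 10))
  plate$labels <- list(baseplate = seq_len(nrow(plate$vertices)))
  landmarks <- list(
    condyle_center_medial = c(0, half, r),
    condyle_center_lateral = c(0, -half, r),
    condyle_radius_medial = r,
    condyle_radius_lateral = r,
    condyle_ml_separation = spec$condyle_ml_separation,
    joint_line_femur = 0,
    baseplate_plane = plane(c(0, 0, 0), c(0, 0, 1)),
    baseplate_ap_depth = spec$baseplate_ap_depth,
    baseplate_ml_width = spec$baseplate_ml_width)
  model <- structure(list(femur = comp, baseplate = plate,
                          landmarks = landmarks, spec = spec, type = "tka"),
                     class = c("tka_model", "knee_model"))
  if (spec$side == "left") model <- mirror_knee_model(model)
  model
}

#' Mirror a knee model across the sagittal plane
#'
#' Maps a right-knee model to a left-knee model (or back): meshes, landmark
#' points and plane normals have their medial-lateral (y) component negated.
#'
#' @param model a `knee_model` or `tka_model`.
#' @return The mirrored model with `spec$side` flipped.
#' @export
mirror_knee_model <- function(model) {
  flip_pt <- function(p) { p[2L] <- -p[2L]; p }
  for (m in intersect(c("femur", "tibia", "baseplate"), names(model)))
    model[[m]] <- mirror_mesh(model[[m]])
  lm <- model$landmarks
  for (nm in names(lm)) {
    x <- lm[[nm]]
    if (inherits(x, "kt_plane")) {
      lm[[nm]] <- plane(flip_pt(x$point), flip_pt(x$normal))
    } else if (is.numeric(x) && length(x) == 3L) {
      lm[[nm]] <- flip_pt(x)
    } else if (is.list(x) && !is.null(x$point)) {
      lm[[nm]] <- list(point = flip_pt(x$point), dir = flip_pt(x$dir))
    }
  }
  model$landmarks <- lm
  model$spec$side <- if (model$spec$side == "right") "left" else "right"
  model
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("<%s knee model> side %s\n",
              if (x$type == "tka") "TKA" else "native", x$spec$side))
  for (m in intersect(c("femur", "tibia", "baseplate"), names(x)))
    cat(" ", m, ": ", nrow(x[[m]]$vertices), " vertices\n", sep = "")
  invisible(x)
}

## ---- trajectory generation -------------------------------------------------

# Imposed internal rotation (deg) at flexion f, relative to extension.
rotation_path_value <- function(f, motion) {
  sched <- motion$flexion_schedule
  fmax <- sched[1L]
  mx <- motion$max_internal_rotation
  if (fmax <= 0) return(rep(0, length(f)))
  if (motion$rotation_path == "progressive") {
    return(mx * f / fmax)
  }
  # screw home: terminal_fraction of the rotation inside the final arc
  flast <- sched[length(sched) - 1L]           # last nonzero schedule angle
  tf <- motion$terminal_fraction
  ifelse(f <= flast,
         tf * mx * f / flast,
         mx * (tf + (1 - tf) * (f - flast) / (fmax - flast)))
}

# Medial condyle posterior shift (mm, >= 0) at flexion f.
medial_shift_value <- function(f, motion) {
  s <- motion$medial_posterior_shift_at_30
  if (s == 0) return(rep(0, length(f)))
  s * pmin(f, 30) / 30
}

#' Generate a ground-truth trajectory for a knee model
#'
#' Produces per-frame rigid poses of the femoral and tibial bodies realizing
#' the motion specification: flexion interpolates the schedule (applied about
#' the trans-condylar-center axis so the condylar sphere centers stay put),
#' internal-external rotation follows the chosen path about the tibial
#' proximal axis, and an optional anterior-posterior translation imposes the
#' medial-condyle posterior shift. The tibia stays at identity; all motion is
#' expressed on the femoral body. Frames at every schedule angle are included
#' exactly, ordered from maximum flexion to extension.
#'
#' @param model a `knee_model` or `tka_model` (right-knee convention; left
#'   models are handled by mirroring on analysis).
#' @param motion a [motion_spec()].
#' @param frames total number of frames; must be at least the number of
#'   schedule angles. Default inserts `frames_per_arc` frames per arc.
#' @return List with `poses` (a [pose_sequence()]) and `truth`, a data frame
#'   with columns `frame`, `flexion_deg`, `true_ie_deg`, `true_ap_med_mm`,
#'   `true_ap_lat_mm` (A-P of the condylar lowest points in the tibial frame).
#' @export
generate_trajectory <- function(model, motion = motion_spec(), frames = NULL) {
  sched <- motion$flexion_schedule
  narc <- length(sched) - 1L
  if (is.null(frames)) frames <- narc * motion$frames_per_arc + 1L
  frames <- as.integer(frames)
  if (frames < length(sched))
    kt_parameter_error(sprintf(
      "frames (%d) must be >= number of schedule angles (%d)", frames, length(sched)))
  # distribute extra frames across arcs, keeping schedule angles exact
  extra <- frames - length(sched)
  per_arc <- rep(extra %/% narc, narc)
  if (extra %% narc) per_arc[seq_len(extra %% narc)] <- per_arc[seq_len(extra %% narc)] + 1L
  flex <- unlist(lapply(seq_len(narc), function(i) {
    head(seq(sched[i], sched[i + 1L], length.out = per_arc[i] + 2L), -1L)
  }))
  flex <- c(flex, sched[length(sched)])

  lm <- model$landmarks
  cm <- lm$condyle_center_medial
  cl <- lm$condyle_center_lateral
  sep <- lm$condyle_ml_separation
  axis_dir <- unit3(cl - cm)
  theta <- rotation_path_value(flex, motion)
  shift <- medial_shift_value(flex, motion)

  fem_body <- if (model$type == "tka") "femoral_component" else "femur"
  tib_body <- if (model$type == "tka") "baseplate" else "tibia"

  rows <- vector("list", length(flex))
  for (i in seq_along(flex)) {
    T_flex <- rotation_about_axis(axis_dir, flex[i], point = cm)
    T_ie <- rotation_about_axis(c(0, 0, 1), -theta[i], point = c(0, 0, 0))
    M <- T_ie %*% T_flex
    # translate so the medial condyle A-P position moves by exactly -shift
    med_now <- transform_points(M, cm)
    tx <- (cm[1L] - shift[i]) - med_now[1L]
    M <- translation_transform(c(tx, 0, 0)) %*% M
    rows[[i]] <- pose_row(i, fem_body, M, flex[i])
  }
  tib_rows <- lapply(seq_along(flex), function(i)
    pose_row(i, tib_body, diag(4), flex[i]))
  poses <- pose_sequence(do.call(rbind, c(rows, tib_rows)))

  truth <- data.frame(frame = seq_along(flex), flexion_deg = flex,
                      true_ie_deg = theta,
                      true_ap_med_mm = cm[1L] - shift,
                      true_ap_lat_mm = cm[1L] - shift - sep * sin(deg2rad(theta)))
  list(poses = poses, truth = truth)
}

#' Apply registration noise to a pose sequence
#'
#' Perturbs every pose row independently: translation noise per axis
#' (in-plane A-P/P-D, out-of-plane M-L) and a small rotation composed on the
#' lab side, with rotation-vector components drawn per axis. Identical seeds
#' give identical output. Flexion annotations are kept: they label which
#' schedule frame an image was selected for, not a measurement (clear the
#' `flexion_deg` column to force recomputation from the noisy poses).
#'
#' @param poses a [pose_sequence()].
#' @param noise a [noise_spec()].
#' @return The perturbed [pose_sequence()].
#' @export
apply_registration_noise <- function(poses, noise = noise_spec()) {
  if (!inherits(noise, "noise_spec")) noise <- do.call(noise_spec, noise)
  if (noise$sigma_translation_inplane == 0 &&
      noise$sigma_translation_outofplane == 0 &&
      noise$sigma_rotation == 0) return(poses)
  set.seed(noise$seed)
  n <- nrow(poses)
  dt <- cbind(rnorm(n, 0, noise$sigma_translation_inplane),
              rnorm(n, 0, noise$sigma_translation_outofplane),
              rnorm(n, 0, noise$sigma_translation_inplane))
  rv <- matrix(rnorm(3L * n, 0, noise$sigma_rotation), ncol = 3L)
  out <- poses
  for (i in seq_len(n)) {
    M <- pose_matrix_row(poses[i, ])
    ang <- sqrt(sum(rv[i, ]^2))
    Rp <- if (ang > 0) rotation_matrix(rv[i, ], ang) else diag(3)
    P <- rigid_transform(Rp, dt[i, ])
    out[i, ] <- pose_row(poses$frame_index[i], poses$body[i], P %*% M,
                         poses$flexion_deg[i])
  }
  pose_sequence(out)
}

#' Generate a synthetic two-group cohort
#'
#' Stand-in for a patient study: `n_per_group` native knees with screw-home
#' rotation paths and `n_per_group` TKA knees with progressive (medial-pivot)
#' paths. Each knee's maximum internal rotation is drawn from its group's
#' normal distribution; geometry can optionally vary between knees. With
#' `geometry_sd = 0` all knees in a group share one mesh model (regenerated
#' geometry would be identical).
#'
#' @param n_per_group knees per group (>= 2).
#' @param activity `"step_up"` or `"chair_rise"`.
#' @param native_rotation,tka_rotation lists `list(mean, sd)` of the
#'   group-level maximum internal rotation distribution (deg). Defaults are
#'   the cohort magnitudes at maximum flexion: native 13.1 (SD 12.0) and TKA
#'   12.3 (SD 4.4) for step up; 12.6 (SD 9.5) and 12.7 (SD 6.2) for chair
#'   rise.
#' @param geometry_sd SD of per-knee condylar radius and separation
#'   variation (mm, default 0).
#' @param noise optional [noise_spec()] applied to every knee's poses (its
#'   seed is re-derived per knee from `seed`).
#' @param frames_per_arc frames per schedule arc.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return An object of class `knee_cohort`: a list of knees, each
#'   `list(id, group, max_internal_rotation, model, poses, truth)`.
#' @export
generate_cohort <- function(n_per_group = 25L,
                            activity = c("step_up", "chair_rise"),
                            native_rotation = NULL, tka_rotation = NULL,
                            geometry_sd = 0, noise = NULL,
                            frames_per_arc = 1L, seed = 1L) {
  activity <- match.arg(activity)
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    kt_parameter_error("'n_per_group' must be >= 2")
  stopifnot_scalar_number(geometry_sd, "geometry_sd", nonneg = TRUE)
  defaults <- if (activity == "step_up") {
    list(native = list(mean = 13.1, sd = 12.0), tka = list(mean = 12.3, sd = 4.4))
  } else {
    list(native = list(mean = 12.6, sd = 9.5), tka = list(mean = 12.7, sd = 6.2))
  }
  native_rotation <- native_rotation %||% defaults$native
  tka_rotation <- tka_rotation %||% defaults$tka
  set.seed(as.integer(seed))
  draws <- list(
    native = rnorm(n_per_group, native_rotation$mean, native_rotation$sd),
    tka = rnorm(n_per_group, tka_rotation$mean, tka_rotation$sd))
  geo <- matrix(rnorm(2L * 2L * n_per_group, 0, geometry_sd), ncol = 2L)
  noise_seeds <- if (!is.null(noise))
    sample.int(.Machine$integer.max, 2L * n_per_group) else NULL

  base_native <- if (geometry_sd == 0) generate_knee_model(knee_spec()) else NULL
  base_tka <- if (geometry_sd == 0) generate_tka_model(tka_spec()) else NULL

  knees <- vector("list", 2L * n_per_group)
  k <- 0L
  for (group in c("native", "tka")) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      if (geometry_sd == 0) {
        model <- if (group == "native") base_native else base_tka
      } else {
        r <- max(5, 22 + geo[k, 1L])
        sp <- max(10, 46 + geo[k, 2L])
        model <- if (group == "native") {
          generate_knee_model(knee_spec(medial_condyle_radius = r,
                                        lateral_condyle_radius = r,
                                        condyle_ml_separation = sp))
        } else {
          generate_tka_model(tka_spec(medial_condyle_radius = r,
                                      condyle_ml_separation = sp))
        }
      }
      motion <- motion_spec(activity = activity,
                            rotation_path = if (group == "native") "screw_home" else "progressive",
                            max_internal_rotation = draws[[group]][i],
                            frames_per_arc = frames_per_arc)
      traj <- generate_trajectory(model, motion)
      if (!is.null(noise)) {
        ns <- noise
        ns$seed <- noise_seeds[k]
        traj$poses <- apply_registration_noise(traj$poses, ns)
      }
      knees[[k]] <- list(id = sprintf("%s_%02d", group, i), group = group,
                         max_internal_rotation = draws[[group]][i],
                         model = model, poses = traj$poses, truth = traj$truth)
    }
  }
  structure(knees, class = "knee_cohort")
}
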