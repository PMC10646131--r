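# Anatomic axes, flexion angle, femoral sagittal frame, medial plateau
# plane, the simulated tibial resection plane, and the tibial coordinate
# system. All constructions are rigid-motion equivariant: they use only the
# mesh geometry (and labelled patches), never absolute coordinates, except
# where a proximal-direction hint is required and supplied explicitly.

#' Varus-valgus resection search parameters
#'
#' Controls the simulated tibial resection: the plane starts parallel to the
#' medial articular surface 10 mm distal to the medial condyle center, and
#' its varus-valgus angle is adjusted in whole increments until the medial
#' and lateral condylar thicknesses agree within the tolerance.
#'
#' @param distal_offset distal translation from the medial condyle center
#'   (mm, > 0).
#' @param vv_increment varus-valgus adjustment increment (deg, > 0).
#' @param thickness_tolerance admissible medial-lateral thickness imbalance
#'   (mm, > 0).
#' @param vv_search_limit largest adjustment magnitude tried (deg).
#' @return A validated list of class `resection_params`.
#' @export
resection_params <- function(distal_offset = 10, vv_increment = 2,
                             thickness_tolerance = 0.5, vv_search_limit = 10) {
  stopifnot_scalar_number(distal_offset, "distal_offset", positive = TRUE)
  stopifnot_scalar_number(vv_increment, "vv_increment", positive = TRUE)
  stopifnot_scalar_number(thickness_tolerance, "thickness_tolerance", positive = TRUE)
  stopifnot_scalar_number(vv_search_limit, "vv_search_limit", positive = TRUE)
  structure(list(distal_offset = distal_offset, vv_increment = vv_increment,
                 thickness_tolerance = thickness_tolerance,
                 vv_search_limit = vv_search_limit),
            class = "resection_params")
}

#' Cross-section midpoint of a bone at a level plane
#'
#' Intersects the mesh with the plane and returns the area centroid of the
#' largest closed intersection contour (a point on the plane). The area
#' centroid, unlike the mean of contour vertices, is independent of mesh
#' resolution.
#'
#' @param mesh a [surface_mesh()].
#' @param level_plane a [plane()].
#' @return Length-3 point (mm).
#' @export
cross_section_midpoint <- function(mesh, level_plane) {
  contours <- mesh_cross_section(mesh, level_plane)
  ct <- largest_closed_contour(contours, level_plane)
  polygon_area_centroid(ct$points, level_plane)$centroid
}

#' Anatomic axis of a bone shaft
#'
#' The line through the cross-section midpoints at two levels measured from
#' the joint line along the shaft, directed away from the joint (the chord,
#' not a tangent, when the shaft is bowed).
#'
#' @param mesh a [surface_mesh()].
#' @param joint_line a point on the joint line (mm).
#' @param levels two distinct positive distances from the joint line (mm),
#'   e.g. `c(70, 120)` for the femur or `c(50, 120)` for the tibia.
#' @param away unit direction from the joint into the shaft (+proximal for
#'   the femur, -proximal i.e. distal for the tibia).
#' @return List `(point, dir)`: `point` is the midpoint at the nearer level
#'   and `dir` the unit direction away from the joint.
#' @export
anatomic_axis <- function(mesh, joint_line, levels, away = c(0, 0, 1)) {
  levels <- as.numeric(levels)
  if (length(levels) != 2L || any(levels <= 0))
    kt_parameter_error("'levels' must be two positive distances from the joint line")
  if (abs(levels[1L] - levels[2L]) < 1e-9)
    kt_parameter_error("the two axis levels must be distinct")
  away <- unit3(away)
  levels <- sort(levels)
  mids <- lapply(levels, function(lv) {
    pl <- plane(as.numeric(joint_line) + lv * away, away)
    tryCatch(cross_section_midpoint(mesh, pl),
             kneetrack_geometry_error = function(e) kt_geometry_error(
               sprintf("no closed cross-section at the %g mm level: %s",
                       lv, conditionMessage(e))))
  })
  list(point = mids[[1L]], dir = unit3(mids[[2L]] - mids[[1L]]))
}

#' Knee flexion angle from anatomic axes
#'
#' Flexion is 180 degrees minus the included angle between the femoral and
#' tibial anatomic axes, each directed away from the joint, so a straight
#' limb reads 0. Symmetric in its arguments and invariant to axis scaling.
#'
#' @param femur_axis,tibia_axis axis objects (`list(point, dir)`) or bare
#'   direction vectors, each directed away from the joint.
#' @return Flexion angle in degrees, in `[0, 180)`.
#' @export
flexion_angle <- function(femur_axis, tibia_axis) {
  dir_of <- function(a) if (is.list(a)) a$dir else a
  180 - vector_angle(dir_of(femur_axis), dir_of(tibia_axis))
}

#' Femoral sagittal frame from the posterior condylar surfaces
#'
#' Fits spheres to the two labelled condylar patches; the sagittal-plane
#' normal (the medial-lateral direction, +lateral) is the unit vector joining
#' the fitted centers. The proximal direction comes from the shaft patch's
#' principal axis (oriented away from the condyles) and the anterior
#' direction completes the right-handed (ML, AP, PD) triad.
#'
#' @param femur a [surface_mesh()] with labels `condyle_medial`,
#'   `condyle_lateral` and (for the proximal direction) `shaft`, or a
#'   `knee_model` whose `femur` carries them.
#' @param max_fit_rms largest admissible sphere-fit RMS (mm).
#' @return List of class `anatomic_frame`: `origin` (between the condylar
#'   centers), unit axes `ml`, `ap`, `pd`, per-condyle fits
#'   (`center_medial`, `center_lateral`, `radius_medial`, `radius_lateral`)
#'   and the fit RMS values.
#' @export
femoral_sagittal_frame <- function(femur, max_fit_rms = 1) {
  if (inherits(femur, "knee_model")) femur <- femur$femur
  fits <- lapply(c("condyle_medial", "condyle_lateral"), function(lb) {
    pts <- mesh_patch(femur, lb)
    if (nrow(pts) < 50L)
      kt_geometry_error(sprintf("condylar patch '%s' has only %d vertices (< 50)",
                                lb, nrow(pts)))
    fit <- fit_sphere(pts)
    if (fit$rms > max_fit_rms)
      kt_geometry_error(sprintf("sphere fit RMS %.2f mm on '%s' exceeds %g mm",
                                fit$rms, lb, max_fit_rms))
    fit
  })
  cm <- fits[[1L]]$center; cl <- fits[[2L]]$center
  ml <- unit3(cl - cm)
  shaft_pts <- if (!is.null(femur$labels$shaft)) mesh_patch(femur, "shaft") else NULL
  pd_raw <- if (!is.null(shaft_pts)) {
    ctr <- colMeans(shaft_pts)
    ax <- svd(sweep(shaft_pts, 2L, ctr), nu = 0L)$v[, 1L]
    if (sum(ax * (ctr - (cm + cl) / 2)) < 0) ax <- -ax
    ax
  } else c(0, 0, 1)
  pd <- unit3(pd_raw - sum(pd_raw * ml) * ml)
  ap <- cross3(pd, ml)                        # (ml, ap, pd) right-handed
  structure(list(origin = (cm + cl) / 2, ml = ml, ap = ap, pd = pd,
                 center_medial = cm, center_lateral = cl,
                 radius_medial = fits[[1L]]$radius,
                 radius_lateral = fits[[2L]]$radius,
                 rms_medial = fits[[1L]]$rms, rms_lateral = fits[[2L]]$rms),
            class = "anatomic_frame")
}

#' Medial tibial articular plane
#'
#' Least-squares plane of the labelled medial articular patch, oriented
#' proximally. When a sagittal frame is supplied, the fitted normal is
#' re-orthogonalized to be perpendicular to the sagittal plane by a rotation
#' about the anterior-posterior direction only (its ML component is removed
#' while the AP component is kept).
#'
#' @param tibia a [surface_mesh()] with label `plateau_medial`, or a
#'   `knee_model`.
#' @param sagittal optional [femoral_sagittal_frame()].
#' @return A [plane()] through the patch centroid, with attribute `rms`.
#' @export
medial_plateau_plane <- function(tibia, sagittal = NULL) {
  if (inherits(tibia, "knee_model")) tibia <- tibia$tibia
  pts <- mesh_patch(tibia, "plateau_medial")
  pd_hint <- if (is.null(sagittal)) c(0, 0, 1) else sagittal$pd
  pl <- fit_plane(pts, orient = pd_hint)
  if (is.null(sagittal)) return(pl)
  n <- pl$normal
  a_ap <- sum(n * sagittal$ap)
  a_pd <- sum(n * sagittal$pd)
  s <- sqrt(sum(n * sagittal$ml)^2 + a_pd^2)   # rotate (ML,PD) components onto PD
  n2 <- unit3(a_ap * sagittal$ap + s * sagittal$pd)
  out <- plane(pl$point, n2)
  attr(out, "rms") <- attr(pl, "rms")
  out
}

#' Simulate the tibial resection plane with varus-valgus balancing
#'
#' Starts from a plane parallel to the medial articular surface translated
#' `distal_offset` mm distally from the medial tibial condyle center, then
#' adjusts its varus-valgus angle in whole increments (order 0, +i, -i, +2i,
#' -2i, ... nearest-to-neutral first) about the anterior-posterior axis
#' through the medial condyle center, until the medial and lateral condylar
#' thicknesses (point-to-plane distances from the condyle centers) agree
#' within the tolerance. Positive adjustments rotate by the right-hand rule
#' about the anterior direction (medial side distal / lateral side proximal
#' in the right-knee convention).
#'
#' @param tibia a `knee_model` (native) or a [surface_mesh()] carrying
#'   `plateau_medial` / `plateau_lateral` labels.
#' @param params a [resection_params()].
#' @param sagittal optional [femoral_sagittal_frame()] supplying the AP
#'   pivot direction; defaults to the model x axis.
#' @return An object of class `resection_plane`: the [plane()] fields plus
#'   `vv_applied` (deg), `thickness_medial`, `thickness_lateral` (mm) and
#'   the condyle centers used.
#' @export
simulate_resection_plane <- function(tibia, params = resection_params(),
                                     sagittal = NULL) {
  mesh <- if (inherits(tibia, "knee_model")) tibia$tibia else tibia
  med_pts <- mesh_patch(mesh, "plateau_medial")
  lat_pts <- mesh_patch(mesh, "plateau_lateral")
  med_ctr <- colMeans(med_pts)
  lat_ctr <- colMeans(lat_pts)
  mp <- medial_plateau_plane(mesh, sagittal)
  ap_dir <- if (is.null(sagittal)) c(1, 0, 0) else sagittal$ap
  base <- plane(med_ctr - params$distal_offset * mp$normal, mp$normal)
  k <- floor(params$vv_search_limit / params$vv_increment)
  cand <- c(0, as.vector(rbind(seq_len(k), -seq_len(k))) * params$vv_increment)
  best <- NULL
  for (vv in cand) {
    pl <- if (vv == 0) base else
      transform_plane(base, rotation_about_axis(ap_dir, vv, point = med_ctr))
    th_m <- abs(plane_distance(pl, med_ctr))
    th_l <- abs(plane_distance(pl, lat_ctr))
    imb <- abs(th_m - th_l)
    if (is.null(best) || imb < best$imbalance)
      best <- list(vv = vv, imbalance = imb)
    if (imb <= params$thickness_tolerance) {
      stopifnot(imb <= params$thickness_tolerance)  # post-condition
      return(structure(list(point = pl$point, normal = pl$normal,
                            vv_applied = vv,
                            thickness_medial = th_m, thickness_lateral = th_l,
                            condyle_center_medial = med_ctr,
                            condyle_center_lateral = lat_ctr),
                       class = c("resection_plane", "kt_plane")))
    }
  }
  kt_convergence_error(sprintf(
    paste("no varus-valgus adjustment within +-%g deg balances the condylar",
          "thicknesses to %g mm; best imbalance %.2f mm at %g deg"),
    params$vv_search_limit, params$thickness_tolerance,
    best$imbalance, best$vv),
    best_vv = best$vv, best_imbalance = best$imbalance)
}

#' Tibial coordinate system from the resection contour
#'
#' Intersects the tibia with the resection plane; the center of the bounding
#' box of the largest closed contour - axis-aligned with the medial-lateral
#' and anterior-posterior directions of the femoral sagittal frame projected
#' into the plane - is the origin. Axes are orthonormal and right-handed
#' with ML (+lateral), AP (+anterior, in the resection plane) and PD
#' (+proximal, the plane normal). The contour's A-P extent is recorded as
#' the native plateau A-P dimension used for standardization.
#'
#' @param resection a `resection_plane` (or any [plane()] with proximal
#'   normal).
#' @param tibia a `knee_model` or tibial [surface_mesh()].
#' @param sagittal optional [femoral_sagittal_frame()] supplying the AP
#'   direction hint; defaults to the model x axis.
#' @return An object of class `tibial_frame`: `origin`, unit axes `ml`,
#'   `ap`, `pd`, and `ap_extent` (mm).
#' @export
tibial_frame <- function(resection, tibia, sagittal = NULL) {
  mesh <- if (inherits(tibia, "knee_model")) tibia$tibia else tibia
  pl <- plane(resection$point, resection$normal)
  ct <- largest_closed_contour(mesh_cross_section(mesh, pl), pl)
  ap_hint <- if (is.null(sagittal)) c(1, 0, 0) else sagittal$ap
  pd <- pl$normal
  ap <- unit3(ap_hint - sum(ap_hint * pd) * pd)
  ml <- cross3(ap, pd)                         # ml x ap = pd
  rel <- sweep(ct$points, 2L, pl$point)
  u <- as.numeric(rel %*% ml)
  v <- as.numeric(rel %*% ap)
  ctr <- pl$point + mean(range(u)) * ml + mean(range(v)) * ap
  structure(list(origin = ctr, ml = ml, ap = ap, pd = pd,
                 ap_extent = diff(range(v))),
            class = "tibial_frame")
}

#' TKA baseplate reference frame
#'
#' Bounding-box frame of the tibial baseplate: the origin is the center of
#' the axis-aligned bounding box, the ML midline is the medial-lateral
#' reference, and the reference plane for lowest points is the baseplate top
#' surface.
#'
#' @param model a `tka_model`.
#' @return A `tibial_frame` plus attribute-free fields `reference_plane` and
#'   `ap_extent` (the baseplate A-P depth).
#' @export
baseplate_frame <- function(model) {
  bb <- mesh_bbox(model$baseplate)
  ctr <- colMeans(bb)
  structure(list(origin = ctr,
                 ml = c(0, -1, 0), ap = c(1, 0, 0), pd = c(0, 0, 1),
                 ap_extent = bb[2L, 1L] - bb[1L, 1L],
                 reference_plane = plane(c(ctr[1L], ctr[2L], bb[2L, 3L]),
                                         c(0, 0, 1))),
            class = "tibial_frame")
}
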