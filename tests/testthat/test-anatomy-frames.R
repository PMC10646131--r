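# Frame constructions: cross-section midpoints, anatomic axes, flexion,
# sagittal frame, plateau plane, resection balancing, tibial frame.

test_that("cross-section midpoint of a cylinder lies on its axis and translates with it", {
  cyl <- cylinder_mesh(15, z_from = -60, z_to = 60, n_seg = 128)
  pl <- plane(c(0, 0, 17), c(0, 0, 1))
  mid <- cross_section_midpoint(cyl, pl)
  expect_lt(sqrt(sum((mid - c(0, 0, 17))^2)), 1e-6)

  shifted <- transform_mesh(cyl, translation_transform(c(5, 0, 0)))
  mid2 <- cross_section_midpoint(shifted, pl)
  expect_equal(mid2 - mid, c(5, 0, 0), tolerance = 1e-9)
})

test_that("cross-section midpoint matches the brute-force polygon centroid on a femur", {
  m <- cached_model("coarse")
  pl <- plane(c(0, 0, 70), c(0, 0, 1))
  mid <- cross_section_midpoint(m$femur, pl)
  cts <- kneetrack:::mesh_cross_section(m$femur, pl)
  areas <- vapply(cts, function(ct)
    kneetrack:::polygon_area_centroid(ct$points, pl)$area, numeric(1))
  pts2 <- cts[[which.max(areas)]]$points[, 1:2]  # plane is z = 70
  expect_equal(mid[1:2], oracle_polygon_centroid(pts2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(mid[3], 70, tolerance = 1e-9)
})

test_that("cross-section errors when the plane misses the mesh", {
  cyl <- cylinder_mesh(15, z_from = 0, z_to = 50)
  expect_error(cross_section_midpoint(cyl, plane(c(0, 0, 100), c(0, 0, 1))),
               class = "kneetrack_geometry_error")
})

test_that("anatomic axis is the chord through the level midpoints, not a tangent", {
  # straight shaft: axis parallel to z
  straight <- cylinder_mesh(14, z_from = 20, z_to = 150, n_seg = 96)
  ax <- anatomic_axis(straight, c(0, 0, 0), c(70, 120), away = c(0, 0, 1))
  expect_lt(vector_angle(ax$dir, c(0, 0, 1)), 0.1)

  # 3-degree bend at 90 mm, between the level planes: expect the chord
  bend_at <- 90
  lower <- cbind(0, 0, seq(20, bend_at, by = 5))
  bend_dir <- c(sin(3 * pi / 180), 0, cos(3 * pi / 180))
  upper <- t(vapply(seq(5, 70, by = 5), function(s) c(0, 0, bend_at) + s * bend_dir,
                    numeric(3)))
  bent <- tube_mesh(rbind(lower, upper), 14, n_seg = 96)
  ax2 <- anatomic_axis(bent, c(0, 0, 0), c(70, 120), away = c(0, 0, 1))
  # analytic midpoints: at 70 on the straight leg; at 120 on the bent leg
  # (ring centers offset; the oblique cut of the bent tube stays centered on
  # the centerline to first order)
  m70 <- c(0, 0, 70)
  s_at <- (120 - bend_at) / cos(3 * pi / 180)
  m120 <- c(0, 0, bend_at) + s_at * bend_dir
  chord <- (m120 - m70) / sqrt(sum((m120 - m70)^2))
  expect_lt(vector_angle(ax2$dir, chord), 0.15)
  # and the chord is distinct from the distal tangent (0 deg) by ~1.2 deg
  expect_gt(vector_angle(ax2$dir, c(0, 0, 1)), 0.5)

  expect_error(anatomic_axis(straight, c(0, 0, 0), c(70, 70)),
               class = "kneetrack_parameter_error")
})

test_that("flexion angle is 0 for a straight limb, 90 at right angles, symmetric and scale-free", {
  f_ax <- list(point = c(0, 0, 0), dir = c(0, 0, 1))
  t_ax <- list(point = c(0, 0, 0), dir = c(0, 0, -1))
  expect_equal(flexion_angle(f_ax, t_ax), 0)
  expect_equal(flexion_angle(c(1, 0, 0), c(0, 0, -1)), 90)
  expect_equal(flexion_angle(c(1, 0, 2), c(0, 1, -3)),
               flexion_angle(c(0, 1, -3), c(1, 0, 2)))
  expect_equal(flexion_angle(c(2, 0, 4), c(0, 5, -15)),
               flexion_angle(c(1, 0, 2), c(0, 1, -3)))
  expect_error(flexion_angle(c(0, 0, 0), c(0, 0, 1)),
               class = "kneetrack_parameter_error")
})

test_that("a knee hinged by 45 degrees reads 45 from the recomputed axes", {
  m <- cached_model("coarse")
  lm <- m$landmarks
  hinge <- rotation_about_axis(c(0, 1, 0), 45, point = lm$condyle_center_medial)
  fem <- transform_mesh(m$femur, hinge)
  f_ax <- anatomic_axis(fem, transform_points(hinge, c(0, 0, 0)) ,
                        c(70, 120), away = as.numeric(hinge[1:3, 1:3] %*% c(0, 0, 1)))
  t_ax <- anatomic_axis(m$tibia, c(0, 0, 0), c(50, 120), away = c(0, 0, -1))
  expect_equal(flexion_angle(f_ax, t_ax), 45, tolerance = 0.5)
})

test_that("sagittal frame recovers the condylar center line and de-rotates a spun model", {
  m <- cached_model("coarse")
  sf <- femoral_sagittal_frame(m$femur)
  truth_ml <- kneetrack:::unit3(m$landmarks$condyle_center_lateral -
                                  m$landmarks$condyle_center_medial)
  expect_lt(vector_angle(sf$ml, truth_ml), 0.5)

  spin <- rotation_about_axis(c(0, 0, 1), 10)
  sf2 <- femoral_sagittal_frame(transform_mesh(m$femur, spin))
  expect_lt(vector_angle(sf2$ml, as.numeric(spin[1:3, 1:3] %*% sf$ml)), 0.5)
  expect_lt(vector_angle(sf2$pd, sf$pd), 0.5)   # spin is about PD

  # degenerate patch: fewer than 50 vertices
  small <- m$femur
  small$labels$condyle_medial <- small$labels$condyle_medial[1:20]
  expect_error(femoral_sagittal_frame(small), class = "kneetrack_geometry_error")
})

test_that("medial plateau plane is exact on the planar patch and noise-robust", {
  m <- cached_model("coarse")
  pl <- medial_plateau_plane(m$tibia)
  expect_lt(vector_angle(pl$normal, c(0, 0, 1)), 1e-6)
  expect_lt(attr(pl, "rms"), 1e-9)

  # +-0.2 mm vertex noise: tilt under 0.5 degrees
  set.seed(4)
  noisy <- m$tibia
  idx <- noisy$labels$plateau_medial
  noisy$vertices[idx, 3] <- noisy$vertices[idx, 3] + runif(length(idx), -0.2, 0.2)
  pl2 <- medial_plateau_plane(noisy)
  expect_lt(vector_angle(pl2$normal, c(0, 0, 1)), 0.5)

  # re-orthogonalization only rotates about AP: the AP component of the
  # normal is preserved while the ML component is zeroed
  sf <- femoral_sagittal_frame(m$femur)
  tilted <- m$tibia
  R <- rotation_matrix(c(1, 0, 0), 4)   # tilt patch about AP
  tilted$vertices[idx, ] <- t(R %*% t(tilted$vertices[idx, ]))
  pl3 <- medial_plateau_plane(tilted, sf)
  expect_lt(abs(sum(pl3$normal * sf$ml)), 1e-9)
  raw <- kneetrack:::fit_plane(tilted$vertices[idx, ], orient = c(0, 0, 1))
  expect_equal(sum(pl3$normal * sf$ap), sum(raw$normal * sf$ap), tolerance = 1e-9)
})

test_that("resection balancing matches the exhaustive sweep oracle across plateau deformities", {
  for (varus in c(0, 3, 4)) {
    m <- generate_knee_model(coarse_spec(plateau_varus_angle = varus))
    med <- colMeans(mesh_patch(m$tibia, "plateau_medial"))
    lat <- colMeans(mesh_patch(m$tibia, "plateau_lateral"))
    want <- oracle_vv_sweep(med, lat, c(0, 0, 1), c(1, 0, 0))
    res <- simulate_resection_plane(m)
    expect_equal(res$vv_applied, want$vv)
    expect_lte(abs(res$thickness_medial - res$thickness_lateral), 0.5)
    expect_equal(res$thickness_medial, 10, tolerance = 1e-6)
  }
  # extreme deformity: no adjustment within +-10 degrees can balance
  m30 <- generate_knee_model(coarse_spec(plateau_varus_angle = 30))
  expect_error(simulate_resection_plane(m30),
               class = "kneetrack_convergence_error")
})

test_that("tibial frame origin and A-P extent follow the resection contour", {
  m <- cached_model("coarse")
  sf <- femoral_sagittal_frame(m$femur)
  res <- simulate_resection_plane(m, sagittal = sf)
  fr <- tibial_frame(res, m, sf)
  expect_equal(fr$origin, c(0, 0, -10), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fr$ap_extent, 50, tolerance = 1e-6)
  # orthonormal right-handed axes with AP in the plane
  expect_equal(crossprod(cbind(fr$ml, fr$ap, fr$pd)), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(kneetrack:::cross3(fr$ml, fr$ap), fr$pd, tolerance = 1e-9)
  expect_lt(abs(sum(fr$ap * res$normal)), 1e-9)

  # translating the tibia translates the origin equally
  shifted <- transform_mesh(m$tibia, translation_transform(c(3, 0, 0)))
  res2 <- res; res2$point <- res$point  # same plane still cuts the slab
  fr2 <- tibial_frame(res2, shifted, sf)
  expect_equal(fr2$origin - fr$origin, c(3, 0, 0), tolerance = 1e-6)

  # brute-force extremum oracle for the A-P dimension
  ct <- kneetrack:::largest_closed_contour(
    kneetrack:::mesh_cross_section(m$tibia, plane(res$point, res$normal)),
    plane(res$point, res$normal))
  v <- as.numeric(sweep(ct$points, 2, res$point) %*% fr$ap)
  expect_equal(fr$ap_extent, max(v) - min(v), tolerance = 1e-12)
})

test_that("frame constructions are rigid-motion equivariant", {
  m <- cached_model("coarse")
  sf <- femoral_sagittal_frame(m$femur)
  res <- simulate_resection_plane(m, sagittal = sf)
  fr <- tibial_frame(res, m, sf)
  set.seed(9)
  Tm <- random_pose(t_range = 30)
  m2 <- m
  m2$femur <- transform_mesh(m$femur, Tm)
  m2$tibia <- transform_mesh(m$tibia, Tm)
  sf2 <- femoral_sagittal_frame(m2$femur)
  res2 <- simulate_resection_plane(m2, sagittal = sf2)
  fr2 <- tibial_frame(res2, m2, sf2)
  R <- Tm[1:3, 1:3]
  expect_equal(res2$vv_applied, res$vv_applied)
  expect_lt(max(abs(fr2$origin - transform_points(Tm, fr$origin))), 1e-6)
  expect_lt(vector_angle(fr2$ml, as.numeric(R %*% fr$ml)), 1e-4)
  expect_lt(vector_angle(fr2$pd, as.numeric(R %*% fr$pd)), 1e-4)
  expect_equal(fr2$ap_extent, fr$ap_extent, tolerance = 1e-6)
})
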