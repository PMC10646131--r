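# Generator contracts: spec validation, closed-form landmark agreement,
# trajectory path shapes, noise model statistics, cohort reproducibility.

test_that("knee_spec validates its fields and names the offender", {
  expect_s3_class(knee_spec(), "knee_spec")
  expect_error(knee_spec(medial_condyle_radius = -1),
               class = "kneetrack_parameter_error")
  expect_error(knee_spec(shaft_length_tibia = 100), "shaft_length_tibia",
               class = "kneetrack_parameter_error")
  expect_error(knee_spec(plateau_ap_depth = 0), "plateau_ap_depth",
               class = "kneetrack_parameter_error")
})

test_that("generated bodies are edge-closed meshes", {
  m <- cached_model("coarse")
  # every labelled body of the femur and tibia is a closed sub-mesh; check
  # the merged meshes as a whole (each edge borders exactly two faces)
  expect_true(kneetrack:::mesh_is_closed(m$femur))
  expect_true(kneetrack:::mesh_is_closed(m$tibia))
})

test_that("symmetric spec gives equal condylar thickness above any plateau-parallel plane", {
  m <- cached_model("coarse")
  lm <- m$landmarks
  # equal radii, 0 varus: analytic condyle centers sit at equal heights and
  # the plateau patches are coplanar, so thickness above z = const is equal
  expect_equal(lm$condyle_center_medial[3], lm$condyle_center_lateral[3])
  med <- mesh_patch(m$tibia, "plateau_medial")
  lat <- mesh_patch(m$tibia, "plateau_lateral")
  expect_equal(max(abs(med[, 3])), 0)
  expect_equal(max(abs(lat[, 3])), 0)
})

test_that("mesh lowest point of the medial condyle matches sphere tangency within 0.1 mm", {
  m <- cached_model("fine")
  lm <- m$landmarks
  ref <- plane(c(0, 0, 0), c(0, 0, 1))
  lp <- lowest_point(mesh_patch(m$femur, "condyle_medial"), diag(4), ref)
  expected <- lm$condyle_center_medial - lm$condyle_radius_medial * c(0, 0, 1)
  expect_lt(sqrt(sum((lp - expected)^2)), 0.1)
})

test_that("analytic landmarks agree with mesh-derived sphere fits", {
  m <- cached_model("coarse")
  for (side in c("medial", "lateral")) {
    fit <- kneetrack:::fit_sphere(mesh_patch(m$femur, paste0("condyle_", side)))
    expect_lt(sqrt(sum((fit$center - m$landmarks[[paste0("condyle_center_", side)]])^2)),
              0.1)
  }
})

test_that("left knees are sagittal mirrors of right knees", {
  right <- cached_model("coarse")
  left <- generate_knee_model(coarse_spec(side = "left"))
  expect_equal(left$femur$vertices[, 2], -right$femur$vertices[, 2])
  expect_equal(left$landmarks$condyle_center_medial,
               right$landmarks$condyle_center_medial * c(1, -1, 1))
})

test_that("TKA baseplate bounding box has exactly the specified A-P depth", {
  for (depth in c(50, 40)) {
    tk <- generate_tka_model(coarse_tka(baseplate_ap_depth = depth))
    bb <- mesh_bbox(tk$baseplate)
    expect_equal(bb[2, 1] - bb[1, 1], depth)
    # bounding-box center on the plate's centroid axis
    expect_equal(colMeans(bb)[1:2], colMeans(tk$baseplate$vertices)[1:2],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("motion_spec enforces a strictly decreasing schedule in range", {
  expect_error(motion_spec(flexion_schedule = c(60, 60, 0)),
               class = "kneetrack_parameter_error")
  expect_error(motion_spec(flexion_schedule = c(160, 0)),
               class = "kneetrack_parameter_error")
  expect_equal(motion_spec("chair_rise")$flexion_schedule, c(90, 60, 30, 0))
})

test_that("trajectory rotation paths have the stated shapes", {
  m <- cached_model("coarse_tka")
  prog <- motion_spec("step_up", rotation_path = "progressive",
                      max_internal_rotation = 13,
                      medial_posterior_shift_at_30 = 0)
  tr <- generate_trajectory(m, prog)
  # linear in flexion: 6.5 deg at 30 of a 0-60 ramp to 13
  expect_equal(tr$truth$true_ie_deg[tr$truth$flexion_deg == 30], 6.5)
  expect_equal(tr$truth$true_ie_deg[tr$truth$flexion_deg == 0], 0)

  mh <- cached_model("coarse")
  sh <- motion_spec("step_up", rotation_path = "screw_home",
                    max_internal_rotation = 13)
  tr2 <- generate_trajectory(mh, sh)
  th <- tr2$truth$true_ie_deg[match(c(15, 0), tr2$truth$flexion_deg)]
  expect_gte(th[1] - th[2], 0.6 * 13)          # terminal-arc concentration
  expect_equal(tr2$truth$true_ie_deg[tr2$truth$flexion_deg == 60], 13)
  # endpoint equality across paths, given the same maximum rotation
  expect_equal(max(tr$truth$true_ie_deg), max(tr2$truth$true_ie_deg))
})

test_that("trajectory includes every schedule angle and validates frame counts", {
  m <- cached_model("coarse")
  tr <- generate_trajectory(m, motion_spec("chair_rise"), frames = 10)
  expect_true(all(c(90, 60, 30, 0) %in% tr$truth$flexion_deg))
  expect_equal(nrow(tr$truth), 10)
  expect_error(generate_trajectory(m, motion_spec("chair_rise"), frames = 3),
               class = "kneetrack_parameter_error")
})

test_that("registration noise is seeded, zero-sigma-stable, and per-axis calibrated", {
  m <- cached_model("coarse_tka")
  tr <- generate_trajectory(m, motion_spec("step_up", rotation_path = "progressive"),
                            frames = 250)
  zero <- noise_spec(0, 0, 0, seed = 1)
  expect_identical(apply_registration_noise(tr$poses, zero), tr$poses)
  n1 <- apply_registration_noise(tr$poses, noise_spec(seed = 42))
  n2 <- apply_registration_noise(tr$poses, noise_spec(seed = 42))
  expect_identical(n1, n2)
  n3 <- apply_registration_noise(tr$poses, noise_spec(seed = 43))
  expect_false(identical(n1, n3))

  # recover the applied rotation vectors; per-axis SD must match sigma
  np <- apply_registration_noise(tr$poses, noise_spec(sigma_rotation = 0.5, seed = 7))
  rv <- t(vapply(seq_len(nrow(np)), function(i) {
    M0 <- kneetrack:::pose_matrix_row(tr$poses[i, ])
    M1 <- kneetrack:::pose_matrix_row(np[i, ])
    Rp <- M1[1:3, 1:3] %*% t(M0[1:3, 1:3])
    ang <- acos(pmin(1, (sum(diag(Rp)) - 1) / 2))
    ax <- c(Rp[3, 2] - Rp[2, 3], Rp[1, 3] - Rp[3, 1], Rp[2, 1] - Rp[1, 2]) /
      (2 * sin(ang))
    ax * ang * 180 / pi
  }, numeric(3)))
  sds <- apply(rv, 2, sd)
  expect_true(all(sds > 0.45 & sds < 0.55))
})

test_that("cohorts are reproducible and honor the configured rotation spread", {
  co <- generate_cohort(5, seed = 3, frames_per_arc = 1)
  co2 <- generate_cohort(5, seed = 3, frames_per_arc = 1)
  expect_identical(lapply(co, `[`, c("id", "max_internal_rotation")),
                   lapply(co2, `[`, c("id", "max_internal_rotation")))
  expect_error(generate_cohort(1), class = "kneetrack_parameter_error")

  # zero geometric variance: all knees in a group share identical geometry
  ids <- vapply(co, `[[`, character(1), "group")
  native_models <- lapply(co[ids == "native"], `[[`, "model")
  expect_identical(native_models[[1]]$femur$vertices,
                   native_models[[2]]$femur$vertices)

  # configured SD 4.6 at n = 25: sample SD within +-1.5 of the target
  co3 <- generate_cohort(25, native_rotation = list(mean = 13, sd = 4.6),
                         seed = 1, frames_per_arc = 1)
  mx <- vapply(co3[vapply(co3, `[[`, character(1), "group") == "native"],
               `[[`, numeric(1), "max_internal_rotation")
  expect_lt(abs(sd(mx) - 4.6), 1.5)
})
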