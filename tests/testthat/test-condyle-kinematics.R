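# Lowest-point tracking, repeat averaging, standardization, rotation.

make_track <- function(ap_med, ml_med, ap_lat, ml_lat,
                       sched = c(60, 45, 30, 15, 0), ...) {
  condylar_track(data.frame(flexion_deg = sched, ap_med = ap_med,
                            ml_med = ml_med, ap_lat = ap_lat, ml_lat = ml_lat),
                 ...)
}

test_that("lowest point equals sphere tangency, also with a tilted plane", {
  sp <- icosphere(20, center = c(5, -3, 30), edge = 0.3)
  flat <- plane(c(0, 0, 0), c(0, 0, 1))
  lp <- lowest_point(sp, diag(4), flat)
  expect_lt(sqrt(sum((lp - c(5, -3, 10))^2)), 0.1)

  n10 <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  tilted <- plane(c(0, 0, 0), n10)
  lp2 <- lowest_point(sp, diag(4), tilted)
  expect_lt(sqrt(sum((lp2 - (c(5, -3, 30) - 20 * n10))^2)), 0.1)

  expect_error(lowest_point(matrix(numeric(0), 0, 3), diag(4), flat),
               class = "kneetrack_parameter_error")
})

test_that("lowest point equals the brute-force vertex scan with the tie rule", {
  set.seed(21)
  sp <- icosphere(22, center = c(0, 23, 22), edge = 1.5)
  ref <- plane(c(1, 2, -3), c(0.1, -0.05, 1))
  for (i in 1:10) {
    Tm <- random_pose(pivot = c(0, 23, 22))
    got <- lowest_point(sp, Tm, ref)
    want <- oracle_lowest_point(sp$vertices, Tm, c(1, 2, -3), c(0.1, -0.05, 1))
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("condylar positions are translation-equivariant in A-P", {
  m <- cached_model("fine")
  fr <- knee_reference_frames(m)
  p0 <- condylar_positions(m, diag(4), fr$frame, fr$reference)
  p1 <- condylar_positions(m, translation_transform(c(2, 0, 0)), fr$frame,
                           fr$reference)
  expect_equal(p1$ap_med - p0$ap_med, 2, tolerance = 1e-9)
  expect_equal(p1$ap_lat - p0$ap_lat, 2, tolerance = 1e-9)
  expect_equal(p1$ml_med, p0$ml_med, tolerance = 1e-9)
})

test_that("medial-pivot TKA keeps the medial condyle A-P fixed; native shifts it 5.1 mm", {
  tk <- cached_model("fine_tka")
  tr <- generate_trajectory(tk, motion_spec("step_up", rotation_path = "progressive"))
  res <- analyze_knee(tk, tr$poses, "step_up")
  expect_lt(max(abs(res$track$ap_med - res$track$ap_med[res$track$flexion_deg == 0])),
            0.2)

  m <- cached_model("fine")
  tr2 <- generate_trajectory(m, motion_spec("step_up", rotation_path = "screw_home",
                                            medial_posterior_shift_at_30 = 5.1))
  res2 <- analyze_knee(m, tr2$poses, "step_up")
  shift <- res2$track$ap_med[res2$track$flexion_deg == 30] -
    res2$track$ap_med[res2$track$flexion_deg == 0]
  expect_equal(shift, -5.1, tolerance = 0.3)
})

test_that("repeat averaging is the coordinate-wise mean and shrinks noise variance", {
  t1 <- make_track(9, -1, 9, 1)
  t2 <- make_track(10, -1, 10, 1)
  t3 <- make_track(11, -1, 11, 1)
  avg <- average_repeats(list(t1, t2, t3))
  expect_equal(avg$ap_med, rep(10, 5))
  expect_equal(attr(avg, "repeats"), 3L)
  expect_equal(average_repeats(list(t1, t1, t1))$ap_med, t1$ap_med)
  expect_error(average_repeats(list(t1, make_track(1, 0, 1, 0, sched = c(90, 60, 30, 0)))),
               class = "kneetrack_parameter_error")

  # variance of the mean: noisy triplets average to ~ sigma^2 / 3
  set.seed(6)
  sigma <- 0.4
  reps <- replicate(500, {
    tracks <- lapply(1:3, function(i) make_track(9 + rnorm(5, 0, sigma), -1, 9, 1))
    average_repeats(tracks)$ap_med[1]
  })
  expect_equal(var(reps), sigma^2 / 3, tolerance = 0.35)
})

test_that("standardization rescales A-P only and never feeds rotation", {
  tr <- make_track(c(10, 8, 6, 4, 2), -23, c(0, 1, 2, 3, 4), 23)
  std <- standardize_ap(tr, standardization_params(50, 40))
  expect_equal(std$ap_med, tr$ap_med * 1.25)
  expect_equal(std$ml_med, tr$ml_med)
  expect_true(attr(std, "standardized"))
  expect_equal(standardize_ap(tr, standardization_params(50, 50))$ap_med, tr$ap_med)
  expect_error(ie_rotation(std, 60, 0), class = "kneetrack_contract_error")
  # rotation computed before standardizing a copy is unaffected
  expect_equal(ie_rotation(tr, 60, 0), ie_rotation(tr, 60, 0))
})

test_that("ie_rotation recovers an imposed axial rotation and is antisymmetric", {
  sep <- 46
  theta <- c(10, 7, 5, 2, 0)     # imposed internal rotation per schedule angle
  ap_med <- sep / 2 * sin(theta * pi / 180)
  ap_lat <- -sep / 2 * sin(theta * pi / 180)
  ml_med <- -sep / 2 * cos(theta * pi / 180)
  ml_lat <- sep / 2 * cos(theta * pi / 180)
  tr <- make_track(ap_med, ml_med, ap_lat, ml_lat)
  expect_equal(ie_rotation(tr, 60, 0), 10, tolerance = 1e-9)
  expect_equal(ie_rotation(tr, 60, 0), -ie_rotation(tr, 0, 60))
  expect_equal(ie_rotation(tr, 30, 30), 0)
  expect_error(ie_rotation(tr, 90, 0), class = "kneetrack_parameter_error")

  # identical positions at both angles: zero rotation
  same <- make_track(3, -23, 1, 23)
  expect_equal(ie_rotation(same, 45, 15), 0)
})

test_that("rotation profiles have the right arc bookkeeping", {
  m <- cached_model("coarse_tka")
  tr <- generate_trajectory(m, motion_spec("step_up", rotation_path = "progressive",
                                           max_internal_rotation = 13))
  res <- analyze_knee(m, tr$poses, "step_up")
  expect_equal(nrow(res$profile$arcs), 4)
  expect_equal(res$profile$arcs$delta_deg, rep(13 / 4, 4), tolerance = 0.2)
  expect_equal(sum(res$profile$arcs$delta_deg), res$profile$max_flexion_rotation,
               tolerance = 1e-9)
  expect_equal(res$profile$rotation$rotation_deg[res$profile$schedule == 0], 0)

  tr2 <- generate_trajectory(m, motion_spec("chair_rise", rotation_path = "progressive"))
  res2 <- analyze_knee(m, tr2$poses, "chair_rise")
  expect_equal(nrow(res2$profile$arcs), 3)

  # incomplete schedule errors, naming the missing angles
  short <- make_track(1, -23, 0, 23, sched = c(60, 30, 0))
  expect_error(build_rotation_profile(short, "step_up"), "45",
               class = "kneetrack_parameter_error")
})
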