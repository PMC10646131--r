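# Statistical machinery: Welch/pooled comparisons, chi-square, power and
# minimum detectable difference, summaries.

test_that("two-sample test handles identity, summary-matched cohorts, and scale", {
  x <- c(1, 2, 3, 4, 5)
  ht <- two_sample_t(x, x)
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)

  # cohort summaries at maximum flexion (step up): Welch p from the rounded
  # summaries is ~0.76, computed independently from the closed form
  a <- sample_with_moments(25, 12.3, 4.4, seed = 1)
  b <- sample_with_moments(25, 13.1, 12.0, seed = 2)
  want <- oracle_welch(12.3, 4.4, 25, 13.1, 12.0, 25)
  ht2 <- two_sample_t(a, b)
  expect_equal(ht2$statistic, want$t, tolerance = 1e-9)
  expect_equal(ht2$df, want$df, tolerance = 1e-9)
  expect_equal(ht2$p_value, want$p, tolerance = 1e-9)
  expect_equal(ht2$p_value, 0.756, tolerance = 0.005)

  # scale invariance of t
  ht3 <- two_sample_t(2 * a, 2 * b)
  expect_equal(ht3$statistic, ht2$statistic, tolerance = 1e-12)

  # pooled variant matches stats::t.test var.equal
  htp <- two_sample_t(a, b, kind = "pooled")
  expect_equal(htp$df, 48)
  expect_error(two_sample_t(1, x), class = "kneetrack_parameter_error")
})

test_that("chi-square is Pearson without continuity correction", {
  # identical sex proportions: statistic 0, p = 1
  tab <- matrix(c(14, 11, 14, 11), 2)
  ht <- chi_square_test(tab)
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)
  expect_equal(ht$df, 1)

  # hand Pearson computation for a perfectly separated 10/10 table
  ht2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ht2$statistic, 20)

  # transposition symmetry
  tab3 <- matrix(c(8, 3, 5, 9), 2)
  expect_equal(chi_square_test(tab3)$statistic, chi_square_test(t(tab3))$statistic)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)),
               class = "kneetrack_parameter_error")
  expect_error(chi_square_test(matrix(c(1.5, 1, 1, 1), 2)),
               class = "kneetrack_parameter_error")
})

test_that("power and detectable difference follow the noncentral-t geometry", {
  spec <- power_spec()
  # two-sided power at delta 0 equals the test size
  spec2 <- power_spec(sided = "two")
  expect_equal(power_at(0, spec2), 0.05, tolerance = 1e-9)
  # monotone in delta
  deltas <- seq(0, 6, by = 0.5)
  pw <- vapply(deltas, power_at, numeric(1), spec = spec)
  expect_true(all(diff(pw) > 0))
  # MDD brackets the target power
  mdd <- detectable_difference(spec)
  expect_gte(power_at(mdd, spec) + 1e-9, 0.80)
  expect_lt(power_at(mdd - 0.1, spec), 0.80)
  # scale equivariance: doubling both SDs doubles the MDD
  spec_x2 <- power_spec(sd_a = 2 * 2.9, sd_b = 2 * 4.6)
  expect_equal(detectable_difference(spec_x2), 2 * mdd, tolerance = 1e-6)
  # degenerate limit: vanishing SDs
  tiny <- power_spec(sd_a = 1e-6, sd_b = 1e-6)
  expect_lt(detectable_difference(tiny), 1e-4)
  expect_error(power_at(-1, spec), class = "kneetrack_parameter_error")
})

test_that("analytic power agrees with Monte-Carlo across a delta grid", {
  spec <- power_spec()
  set.seed(123)
  nrep <- 20000
  for (delta in c(1.5, 2.8, 4)) {
    xa <- matrix(rnorm(25 * nrep, 0, spec$sd_a), 25)
    xb <- matrix(rnorm(25 * nrep, delta, spec$sd_b), 25)
    va <- apply(xa, 2, var) / 25
    vb <- apply(xb, 2, var) / 25
    tstat <- (colMeans(xb) - colMeans(xa)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / 24 + vb^2 / 24)
    rej <- tstat > qt(0.95, df)
    expect_equal(mean(rej), power_at(delta, spec), tolerance = 0.011)
  }
})

test_that("summaries match the reference implementation", {
  expect_equal(summarize_values(c(1, 2, 3))[c("mean", "sd")], list(mean = 2, sd = 1))
  s <- summarize_values(rep(7, 10))
  expect_equal(s$sd, 0)
  expect_equal(s$q3 - s$q1, 0)
  set.seed(2)
  x <- rnorm(101)
  s2 <- summarize_values(x)
  expect_equal(s2$median, median(x), tolerance = 1e-12)
  expect_equal(c(s2$q1, s2$q3), unname(quantile(x, c(0.25, 0.75))), tolerance = 1e-12)
  expect_equal(s2$sd, sd(x), tolerance = 1e-12)
  expect_error(summarize_values(numeric(0)), class = "kneetrack_parameter_error")
})

test_that("group comparison tabulates max-flexion and per-arc tests", {
  mk_prof <- function(max_rot, path = "progressive") {
    sched <- c(60, 45, 30, 15, 0)
    th <- max_rot * sched / 60
    tr <- condylar_track(data.frame(
      flexion_deg = sched,
      ap_med = 23 * sin(th * pi / 180), ml_med = -23 * cos(th * pi / 180),
      ap_lat = -23 * sin(th * pi / 180), ml_lat = 23 * cos(th * pi / 180)))
    build_rotation_profile(tr, "step_up")
  }
  set.seed(5)
  pa <- lapply(rnorm(6, 12, 2), mk_prof)
  pb <- lapply(rnorm(6, 13, 3), mk_prof)
  cmp <- compare_groups(pa, pb)
  expect_equal(nrow(cmp), 5)    # max flexion + 4 arcs
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_equal(cmp$comparison[1], "max_flexion")
})
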