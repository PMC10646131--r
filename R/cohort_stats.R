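# Group summaries and the study's statistical machinery: two-sample
# comparisons at maximum flexion and per arc of extension, chi-square for
# categorical variables, and the noncentral-t power / minimum detectable
# difference analysis for the two-group design.

#' Power analysis specification
#'
#' Two-group design with unequal group standard deviations; power is
#' computed for the Welch test via the noncentral-t distribution with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param n_per_group subjects per group (default 25).
#' @param alpha significance level (default 0.05).
#' @param target_power required power (default 0.80).
#' @param sd_a,sd_b group standard deviations (deg; defaults 2.9 and 4.6,
#'   the arc-of-extension rotation SDs of the TKA and native groups).
#' @param sided `"one"` (default) or `"two"`.
#' @return A validated list of class `power_spec`.
#' @export
power_spec <- function(n_per_group = 25L, alpha = 0.05, target_power = 0.80,
                       sd_a = 2.9, sd_b = 4.6, sided = c("one", "two")) {
  sided <- match.arg(sided)
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    kt_parameter_error("'n_per_group' must be an integer >= 2")
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) kt_parameter_error("'alpha' must be in (0, 1)")
  stopifnot_scalar_number(target_power, "target_power")
  if (target_power <= 0 || target_power >= 1)
    kt_parameter_error("'target_power' must be in (0, 1)")
  stopifnot_scalar_number(sd_a, "sd_a", positive = TRUE)
  stopifnot_scalar_number(sd_b, "sd_b", positive = TRUE)
  structure(list(n_per_group = n_per_group, alpha = alpha,
                 target_power = target_power, sd_a = sd_a, sd_b = sd_b,
                 sided = sided),
            class = "power_spec")
}

welch_geometry <- function(spec) {
  va <- spec$sd_a^2 / spec$n_per_group
  vb <- spec$sd_b^2 / spec$n_per_group
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (spec$n_per_group - 1) + vb^2 / (spec$n_per_group - 1))
  list(se = se, df = df)
}

#' Power of the two-group comparison at a true difference
#'
#' Rejection probability of the (one- or two-sided) Welch test at true group
#' mean difference `delta`, computed from the noncentral-t distribution with
#' noncentrality `delta / se` and Welch-Satterthwaite degrees of freedom.
#'
#' @param delta true group mean difference (deg, >= 0).
#' @param spec a [power_spec()].
#' @return Rejection probability in `[0, 1]`.
#' @export
power_at <- function(delta, spec = power_spec()) {
  if (!inherits(spec, "power_spec")) spec <- do.call(power_spec, spec)
  stopifnot_scalar_number(delta, "delta", nonneg = TRUE)
  g <- welch_geometry(spec)
  ncp <- delta / g$se
  if (spec$sided == "one") {
    crit <- stats::qt(1 - spec$alpha, g$df)
    1 - stats::pt(crit, g$df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - spec$alpha / 2, g$df)
    (1 - stats::pt(crit, g$df, ncp = ncp)) + stats::pt(-crit, g$df, ncp = ncp)
  }
}

#' Minimum detectable difference
#'
#' The smallest true group difference whose power reaches the target, found
#' by root-finding on the (monotone) noncentral-t power curve.
#'
#' @param spec a [power_spec()].
#' @return Minimum detectable difference (deg).
#' @export
detectable_difference <- function(spec = power_spec()) {
  if (!inherits(spec, "power_spec")) spec <- do.call(power_spec, spec)
  g <- welch_geometry(spec)
  upper <- 20 * g$se
  while (power_at(upper, spec) < spec$target_power) upper <- upper * 2
  stats::uniroot(function(d) power_at(d, spec) - spec$target_power,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Two-sample comparison of group rotation samples
#'
#' Welch's t-test by default (the group variances are grossly unequal in the
#' motivating data); the pooled-variance test is available as an option.
#' Two-sided p-values.
#'
#' @param a,b numeric vectors of per-knee values (deg), each n >= 2.
#' @param kind `"welch"` (default) or `"pooled"`.
#' @return An object of class `kt_test` with `statistic`, `df`, `p_value`,
#'   group means/SDs and the test kind.
#' @export
two_sample_t <- function(a, b, kind = c("welch", "pooled")) {
  kind <- match.arg(kind)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b) ||
      any(!is.finite(c(a, b))))
    kt_parameter_error("both samples need >= 2 finite values")
  ht <- stats::t.test(a, b, var.equal = (kind == "pooled"))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b), kind = kind),
            class = "kt_test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return An object of class `kt_test` with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L))
    kt_parameter_error("'counts' must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    kt_parameter_error("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    kt_parameter_error("all table margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, kind = "chi_square"),
            class = "kt_test")
}

#' @export
print.kt_test <- function(x, ...) {
  cat(sprintf("<%s test> statistic %.4f, df %.2f, p = %.4g\n",
              x$kind, x$statistic, x$df, x$p_value))
  if (!is.null(x$mean_a))
    cat(sprintf("  group A: %.2f +- %.2f (n=%d); group B: %.2f +- %.2f (n=%d)\n",
                x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Summary statistics of a sample
#'
#' Mean, sample SD (n-1), range, median and interquartile range (linear
#' interpolation quantiles).
#'
#' @param values numeric vector, n >= 1.
#' @return Named list `n`, `mean`, `sd`, `min`, `max`, `median`, `q1`, `q3`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    kt_parameter_error("'values' must be a non-empty numeric vector without NA")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       min = min(values), max = max(values),
       median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Compare two groups of rotation profiles
#'
#' Runs the study's comparisons on per-knee [build_rotation_profile()]
#' outputs: a two-sample test of rotation at maximum flexion and one per arc
#' of extension.
#'
#' @param profiles_a,profiles_b lists of `rotation_profile`s sharing an
#'   activity/schedule (groups A and B).
#' @param kind test kind passed to [two_sample_t()].
#' @return Data frame with one row per comparison: `comparison`, group
#'   means/SDs, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(profiles_a, profiles_b, kind = c("welch", "pooled")) {
  kind <- match.arg(kind)
  if (!length(profiles_a) || !length(profiles_b))
    kt_parameter_error("both groups need at least one profile")
  arcs <- profiles_a[[1L]]$arcs$arc
  pull <- function(profiles, arc = NULL) {
    vapply(profiles, function(p) {
      if (is.null(arc)) p$max_flexion_rotation
      else p$arcs$delta_deg[match(arc, p$arcs$arc)]
    }, numeric(1L))
  }
  rows <- list()
  add <- function(label, va, vb) {
    ht <- two_sample_t(va, vb, kind)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, mean_a = ht$mean_a, sd_a = ht$sd_a,
      mean_b = ht$mean_b, sd_b = ht$sd_b,
      statistic = ht$statistic, df = ht$df, p_value = ht$p_value)
  }
  add("max_flexion", pull(profiles_a), pull(profiles_b))
  for (arc in arcs)
    add(paste0("arc_", arc), pull(profiles_a, arc = arc), pull(profiles_b, arc = arc))
  do.call(rbind, rows)
}
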