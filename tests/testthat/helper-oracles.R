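# Test helpers: small/fast model specs and independent oracle
# implementations (kept deliberately separate from the package's own code
# paths: brute-force vertex scans, hand-rolled Rodrigues rotations,
# polygon centroids, closed-form Welch formulas).

# coarse, fast models for geometry tests that do not probe mm-level accuracy
coarse_spec <- function(...) {
  knee_spec(condyle_edge_mm = 1.5, mesh_edge_mm = 2.5, ...)
}
coarse_tka <- function(...) {
  tka_spec(condyle_edge_mm = 1.5, mesh_edge_mm = 2.5, ...)
}

# lazily cached shared models (built once per test run)
cached_model <- local({
  cache <- list()
  function(key = c("coarse", "coarse_tka", "fine", "fine_tka")) {
    key <- match.arg(key)
    if (is.null(cache[[key]]))
      cache[[key]] <<- switch(key,
        coarse = generate_knee_model(coarse_spec()),
        coarse_tka = generate_tka_model(coarse_tka()),
        fine = generate_knee_model(knee_spec()),
        fine_tka = generate_tka_model(tka_spec()))
    cache[[key]]
  }
})

# independent Rodrigues rotation (not the package's rotation_matrix)
oracle_rotmat <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ux <- k[1]; uy <- k[2]; uz <- k[3]
  ct <- cos(th); st <- sin(th); vt <- 1 - ct
  matrix(c(ct + ux^2 * vt, ux * uy * vt - uz * st, ux * uz * vt + uy * st,
           uy * ux * vt + uz * st, ct + uy^2 * vt, uy * uz * vt - ux * st,
           uz * ux * vt - uy * st, uz * uy * vt + ux * st, ct + uz^2 * vt),
         3, 3, byrow = TRUE)
}

# brute-force lowest point with the tie rule, straight from the definition
oracle_lowest_point <- function(verts, pose, plane_point, plane_normal,
                                tie_tol = 0.05) {
  n <- plane_normal / sqrt(sum(plane_normal^2))
  pv <- t(pose[1:3, 1:3] %*% t(verts) + pose[1:3, 4])
  d <- as.numeric(pv %*% n) - sum(plane_point * n)
  tied <- d <= min(d) + tie_tol
  colMeans(pv[tied, , drop = FALSE])
}

# polygon area centroid via independent fan-triangulation accumulation
oracle_polygon_centroid <- function(pts2) {
  n <- nrow(pts2)
  j <- c(2:n, 1)
  cr <- pts2[, 1] * pts2[j, 2] - pts2[j, 1] * pts2[, 2]
  a2 <- sum(cr)
  c(sum((pts2[, 1] + pts2[j, 1]) * cr), sum((pts2[, 2] + pts2[j, 2]) * cr)) / (3 * a2)
}

# closed-form Welch test from summary statistics
oracle_welch <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# construct a sample with exactly the requested mean and SD
sample_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  mean + sd * (z - mean(z)) / stats::sd(z)
}

# uniform-ish random rigid transform around a pivot
random_pose <- function(pivot = c(0, 0, 0), t_range = 20) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, 180)
  R <- oracle_rotmat(ax, ang)
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- pivot - R %*% pivot + stats::runif(3, -t_range, t_range)
  T
}

# exhaustive varus-valgus sweep oracle: recomputes candidate planes itself
# from the analytic patch centroids and reports the first admissible
# adjustment (or NULL), mirroring the stated search order.
oracle_vv_sweep <- function(med_ctr, lat_ctr, med_normal, ap_dir,
                            offset = 10, inc = 2, tol = 0.5, limit = 10) {
  k <- floor(limit / inc)
  cand <- c(0, as.vector(rbind(seq_len(k), -seq_len(k))) * inc)
  p0 <- med_ctr - offset * med_normal
  for (vv in cand) {
    R <- oracle_rotmat(ap_dir, vv)
    pt <- med_ctr + R %*% (p0 - med_ctr)
    nrm <- R %*% med_normal
    th_m <- abs(sum((med_ctr - pt) * nrm))
    th_l <- abs(sum((lat_ctr - pt) * nrm))
    if (abs(th_m - th_l) <= tol) return(list(vv = vv, imbalance = abs(th_m - th_l)))
  }
  NULL
}
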