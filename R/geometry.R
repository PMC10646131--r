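# Low-level 3-D geometry: unit vectors, rigid transforms, planes, and
# least-squares plane / sphere fits. All lengths in mm, all angles in degrees
# at the interfaces (radians only inside formulas).

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (!is.finite(n) || n < 1e-12)
    kt_parameter_error("zero-length vector where a direction is required")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two direction vectors
#'
#' @param a,b numeric length-3 direction vectors (any nonzero magnitude).
#' @return Included angle in degrees, in `[0, 180]`.
#' @export
vector_angle <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  # atan2 form is stable near 0 and 180 degrees
  rad2deg(atan2(sqrt(sum(cross3(a, b)^2)), sum(a * b)))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation about the (not necessarily unit) `axis` by `angle_deg`
#' degrees, right-hand rule.
#'
#' @param axis numeric length-3 axis direction.
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  k <- unit3(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform (4x4) rotating about an axis through a point
#'
#' @param axis numeric length-3 axis direction.
#' @param angle_deg rotation angle in degrees.
#' @param point a point on the rotation axis (default origin).
#' @return A 4x4 homogeneous rigid transform.
#' @export
rotation_about_axis <- function(axis, angle_deg, point = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  rigid_transform(R, as.numeric(point) - as.numeric(R %*% point))
}

#' Build / decompose homogeneous rigid transforms
#'
#' `rigid_transform()` assembles a 4x4 matrix from a rotation and translation,
#' `translation_transform()` is pure translation, and `invert_transform()`
#' inverts exploiting rigidity.
#'
#' @param R 3x3 rotation matrix.
#' @param t numeric length-3 translation (mm).
#' @return A 4x4 homogeneous transform matrix.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4L] <- t
  T
}

#' @rdname rigid_transform
#' @export
translation_transform <- function(t) rigid_transform(diag(3), t)

#' @rdname rigid_transform
#' @param T a 4x4 rigid transform.
#' @export
invert_transform <- function(T) {
  R <- T[1:3, 1:3]
  rigid_transform(t(R), -crossprod(R, T[1:3, 4L])[, 1L])
}

#' Apply a rigid transform to points
#'
#' @param T 4x4 rigid transform (body-local mm coordinates to lab frame).
#' @param pts an n x 3 matrix of points (or a length-3 vector).
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(T, pts) {
  if (is.null(dim(pts))) {
    return(as.numeric(T[1:3, 1:3] %*% pts + T[1:3, 4L]))
  }
  sweep(pts %*% t(T[1:3, 1:3]), 2L, -T[1:3, 4L])
}

check_rotation <- function(R, tol = 1e-6) {
  if (max(abs(crossprod(R) - diag(3))) > tol) return("not orthonormal")
  if (det(R) < 0) return("determinant -1 (reflection)")
  NULL
}

## ---- planes ----------------------------------------------------------------

#' Oriented plane
#'
#' A plane is stored as a point on the plane and a unit normal. Signed
#' distances are positive on the side the normal points to.
#'
#' @param point numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal direction (normalized internally).
#' @return An object of class `kt_plane`.
#' @export
plane <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit3(as.numeric(normal))),
            class = "kt_plane")
}

#' @export
print.kt_plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.2f, %.2f, %.2f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1L], x$point[2L], x$point[3L],
              x$normal[1L], x$normal[2L], x$normal[3L]))
  invisible(x)
}

#' Signed distance from points to a plane
#'
#' @param pl a [plane()].
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return Numeric vector of signed distances (mm), positive along the normal.
#' @export
plane_distance <- function(pl, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1L, 3L)
  as.numeric((pts %*% pl$normal) - sum(pl$point * pl$normal))
}

#' Rigidly transform a plane
#'
#' @param pl a [plane()].
#' @param T 4x4 rigid transform.
#' @return The transformed plane.
#' @export
transform_plane <- function(pl, T) {
  plane(transform_points(T, pl$point), as.numeric(T[1:3, 1:3] %*% pl$normal))
}

# Orthonormal in-plane basis (u, v) with u x v = normal.
plane_basis <- function(pl) {
  n <- pl$normal
  seed <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(seed - sum(seed * n) * n)
  list(u = u, v = cross3(n, u))
}

## ---- fits ------------------------------------------------------------------

#' Least-squares plane fit
#'
#' Total least squares via SVD of the centered points. The returned normal is
#' oriented along `orient` (flipped if necessary).
#'
#' @param pts n x 3 matrix of points, n >= 3.
#' @param orient optional direction the normal should have positive dot
#'   product with.
#' @return A [plane()] with attribute `rms` (mm).
#' @export
fit_plane <- function(pts, orient = NULL) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) kt_geometry_error("plane fit needs at least 3 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr)
  sv <- svd(X, nu = 0L)
  if (sv$d[2L] < 1e-9)
    kt_geometry_error("degenerate (collinear) point set in plane fit")
  n <- sv$v[, 3L]
  if (!is.null(orient) && sum(n * orient) < 0) n <- -n
  pl <- plane(ctr, n)
  attr(pl, "rms") <- sqrt(mean((X %*% n)^2))
  pl
}

#' Least-squares sphere fit
#'
#' Algebraic (linear) least-squares fit of a sphere to points.
#'
#' @param pts n x 3 matrix of points, n >= 4.
#' @return List with `center` (mm), `radius` (mm) and `rms` (mm) residual of
#'   radial distances.
#' @export
fit_sphere <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 4L) kt_geometry_error("sphere fit needs at least 4 points")
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.coef(qr(A), b)
  ctr <- sol[1:3]
  r2 <- sol[4L] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) kt_geometry_error("degenerate sphere fit")
  r <- sqrt(r2)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  list(center = as.numeric(ctr), radius = r, rms = sqrt(mean((d - r)^2)))
}

## ---- planar polygon area / centroid ---------------------------------------

# pts: k x 3 vertices of a closed planar polygon (no repeated last point).
# Returns list(area, centroid) with area >= 0 in mm^2.
polygon_area_centroid <- function(pts, pl) {
  b <- plane_basis(pl)
  rel <- sweep(as.matrix(pts), 2L, pl$point)
  x <- as.numeric(rel %*% b$u)
  y <- as.numeric(rel %*% b$v)
  j <- c(seq_len(length(x))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a2 <- sum(cr)
  if (abs(a2) < 1e-12) return(list(area = 0, centroid = colMeans(pts)))
  cx <- sum((x + x[j]) * cr) / (3 * a2)
  cy <- sum((y + y[j]) * cr) / (3 * a2)
  list(area = abs(a2) / 2,
       centroid = pl$point + cx * b$u + cy * b$v)
}
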