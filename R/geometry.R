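# Elementary 3D geometry: points, planes, rigid and reflection transforms,
# and the step-off / gap decomposition of a displacement vector.

.as_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  p <- as.matrix(p)
  if (ncol(p) != 3) .stop_invalid("points must have 3 columns (x, y, z in mm)")
  if (!all(is.finite(p))) .stop_invalid("non-finite coordinates")
  storage.mode(p) <- "double"
  p
}

.norm3 <- function(v) sqrt(rowSums(.as_pts(v)^2))

.unit <- function(v) {
  v <- .as_pts(v)
  n <- sqrt(rowSums(v^2))
  if (any(n < frac_tol$geometry)) .stop_degenerate("cannot normalise a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean distance between 3D points
#'
#' Distance in millimetres between paired points. Both arguments are recycled
#' row-wise when one is a single point.
#'
#' @param a,b Numeric vectors of length 3 or n x 3 matrices (mm).
#' @return Numeric vector of distances (mm).
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
euclidean_distance <- function(a, b) {
  a <- .as_pts(a); b <- .as_pts(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) .stop_invalid("point sets have different sizes")
  sqrt(rowSums((a - b)^2))
}

#' Decompose a displacement into articular step-off and gap
#'
#' Splits displacement vectors `d` into the component perpendicular to the
#' articular surface (the 3D step-off, `|d . n|`) and the component along the
#' surface (the 3D gap, `||d - (d . n) n||`). The signed normal component is
#' returned alongside (positive along `n`); summaries use the magnitudes.
#'
#' @param d Displacement vector(s), length 3 or n x 3 (mm).
#' @param n Unit articular surface normal(s), length 3 or n x 3.
#' @return A tibble with columns `step_off`, `gap`, `step_signed`,
#'   `displacement` (all mm). Satisfies `step_off^2 + gap^2 = displacement^2`.
#' @examples
#' decompose_displacement(c(1, 2, 2), c(0, 0, 1)) # step 2, gap sqrt(5)
#' @export
decompose_displacement <- function(d, n) {
  d <- .as_pts(d); n <- .as_pts(n)
  if (nrow(n) == 1 && nrow(d) > 1) n <- n[rep(1, nrow(d)), , drop = FALSE]
  if (nrow(d) != nrow(n)) .stop_invalid("d and n have different sizes")
  nn <- sqrt(rowSums(n^2))
  if (any(abs(nn - 1) > 1e-6)) .stop_invalid("n must be unit-norm")
  dn <- rowSums(d * n)
  tang <- d - dn * n
  tibble(
    step_off = abs(dn),
    gap = sqrt(rowSums(tang^2)),
    step_signed = dn,
    displacement = sqrt(rowSums(d^2))
  )
}

#' Construct a plane from a point and normal
#'
#' @param point A point on the plane (mm).
#' @param normal Plane normal; normalised internally.
#' @return A `frac_plane` object.
#' @export
frac_plane <- function(point, normal) {
  point <- drop(.as_pts(point))
  normal <- drop(.unit(normal))
  structure(list(point = point, normal = normal), class = "frac_plane")
}

#' @export
print.frac_plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.3f, %.3f, %.3f) normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Plane through three points
#'
#' @param p1,p2,p3 Non-collinear points (mm).
#' @return A `frac_plane` passing through all three points.
#' @export
plane_from_points <- function(p1, p2, p3) {
  p1 <- drop(.as_pts(p1)); p2 <- drop(.as_pts(p2)); p3 <- drop(.as_pts(p3))
  nrm <- .cross3(p2 - p1, p3 - p1)
  scale <- max(euclidean_distance(p1, p2), euclidean_distance(p1, p3))
  if (sqrt(sum(nrm^2)) < 1e-12 * max(scale^2, 1))
    .stop_degenerate("points are collinear; no unique plane")
  frac_plane(p1, nrm)
}

#' Signed distance of points to a plane
#' @param plane A `frac_plane`.
#' @param pts Points (n x 3, mm).
#' @return Signed distances (mm), positive along the plane normal.
#' @export
plane_distance <- function(plane, pts) {
  pts <- .as_pts(pts)
  drop((pts - matrix(plane$point, nrow(pts), 3, byrow = TRUE)) %*% plane$normal)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Length-3 translation (mm).
#' @return A `frac_rigid` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) || !all(is.finite(rotation)))
    .stop_invalid("rotation must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    .stop_invalid("rotation must be orthonormal with determinant +1")
  translation <- drop(.as_pts(translation))
  structure(list(linear = rotation, translation = translation,
                 kind = "rigid"), class = c("frac_rigid", "frac_transform"))
}

#' Rigid transform from axis-angle rotation about a centre
#'
#' @param axis Rotation axis (normalised internally).
#' @param angle_deg Rotation angle, degrees.
#' @param centre Point the rotation pivots about (mm).
#' @param translation Additional translation applied after rotation (mm).
#' @return A `frac_rigid`.
#' @export
rotation_about <- function(axis, angle_deg, centre = c(0, 0, 0),
                           translation = c(0, 0, 0)) {
  a <- drop(.unit(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  centre <- drop(.as_pts(centre))
  rigid_transform(R, drop(centre - R %*% centre) + drop(.as_pts(translation)))
}

#' Reflection across a plane
#'
#' The mirroring operation used to turn the intact contralateral hemipelvis
#' into a template for the fractured side. Its linear part has determinant -1
#' and applying it twice is the identity.
#'
#' @param plane A `frac_plane` (typically the midsagittal plane).
#' @return A `frac_reflection` object.
#' @export
mirror_transform <- function(plane) {
  if (!inherits(plane, "frac_plane")) .stop_invalid("plane must be a frac_plane")
  n <- plane$normal
  L <- diag(3) - 2 * tcrossprod(n)
  t <- 2 * sum(plane$point * n) * n
  structure(list(linear = L, translation = t, kind = "reflection",
                 plane = plane), class = c("frac_reflection", "frac_transform"))
}

#' Apply a transform to points
#' @param transform A `frac_transform` (rigid or reflection).
#' @param pts Points (n x 3 or length 3, mm).
#' @return Transformed points, same shape convention as matrices n x 3.
#' @export
transform_points <- function(transform, pts) {
  stopifnot(inherits(transform, "frac_transform"))
  pts <- .as_pts(pts)
  pts %*% t(transform$linear) +
    matrix(transform$translation, nrow(pts), 3, byrow = TRUE)
}

#' Compose two transforms (apply `b` first, then `a`)
#' @param a,b `frac_transform` objects.
#' @return The composition a o b.
#' @export
compose_transforms <- function(a, b) {
  L <- a$linear %*% b$linear
  t <- drop(a$linear %*% b$translation) + a$translation
  if (abs(det(L) - 1) < 1e-9) rigid_transform(L, t)
  else structure(list(linear = L, translation = t, kind = "reflection"),
                 class = c("frac_reflection", "frac_transform"))
}

#' Invert a transform
#' @param transform A `frac_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  Li <- t(transform$linear) # orthogonal for both rigid and reflection
  ti <- drop(-Li %*% transform$translation)
  if (transform$kind == "rigid") rigid_transform(Li, ti)
  else structure(list(linear = Li, translation = ti, kind = "reflection"),
                 class = c("frac_reflection", "frac_transform"))
}

#' @export
print.frac_transform <- function(x, ...) {
  cat(sprintf("<%s transform> translation (%.3f, %.3f, %.3f) mm\n",
              x$kind, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Translation magnitude and rotation angle of a rigid transform
#' @param transform A `frac_rigid`.
#' @return Named numeric: `translation_mm`, `rotation_deg`.
#' @export
transform_magnitude <- function(transform) {
  tr <- sum(diag(transform$linear))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  c(translation_mm = sqrt(sum(transform$translation^2)), rotation_deg = ang)
}

#' 4 x 4 homogeneous matrix of a transform
#' @param transform A `frac_transform`.
#' @return A 4 x 4 matrix (row-major semantics when serialised).
#' @export
as_matrix4 <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$linear
  m[1:3, 4] <- transform$translation
  m
}

#' Rebuild a transform from a 4 x 4 matrix
#' @param m A 4 x 4 homogeneous matrix.
#' @return A `frac_transform`.
#' @export
from_matrix4 <- function(m) {
  L <- m[1:3, 1:3]; t <- m[1:3, 4]
  if (det(L) > 0) rigid_transform(L, t)
  else structure(list(linear = L, translation = t, kind = "reflection"),
                 class = c("frac_reflection", "frac_transform"))
}
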