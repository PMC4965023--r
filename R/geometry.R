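# Per-endplate geometric primitives. All coordinates live in a right-handed
# patient frame in millimetres: +x patient left -> right, +y posterior ->
# anterior, +z caudal -> cranial. The transverse plane is normal to +z, the
# coronal plane normal to +y.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length ", what, call. = FALSE)
  v / n
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Fit a least-squares plane to a contour point set
#'
#' The plane point is the vertex mean; the normal is the minimizer of the sum
#' of squared point-plane distances (smallest principal direction of the
#' centred points), flipped into the +z hemisphere so that downstream
#' orientation conventions are deterministic.
#'
#' @param points numeric matrix, one 3-D point (mm) per row; at least 3
#'   non-collinear points.
#' @param level optional level label used in error messages.
#' @return list with `point` (3-vector) and `normal` (unit 3-vector,
#'   `normal[3] >= 0`).
#' @export
fit_endplate_plane <- function(points, level = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    stop("degenerate geometry", level_tag(level), ": need >= 3 points", call. = FALSE)
  }
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x, nu = 0, nv = 3)
  # collinear (or all-coincident) points leave two near-zero singular values
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12) || sv$d[1] < 1e-12) {
    stop("degenerate geometry", level_tag(level),
         ": contour points are collinear or duplicated", call. = FALSE)
  }
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  list(point = ctr, normal = unitize(normal, "plane normal"))
}

level_tag <- function(level) {
  if (is.null(level)) "" else paste0(" at level ", level)
}

# In-plane orthonormal basis (e1, e2) completing `normal` to a right-handed
# triad; deterministic for a fixed normal.
plane_basis <- function(normal) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(ref - sum(ref * normal) * normal, "plane basis")
  e2 <- c(
    normal[2] * e1[3] - normal[3] * e1[2],
    normal[3] * e1[1] - normal[1] * e1[3],
    normal[1] * e1[2] - normal[2] * e1[1]
  )
  cbind(e1, e2)
}

#' Area-weighted centroid of a closed planar contour
#'
#' Projects the contour into its best-fit plane and evaluates the polygon
#' (shoelace) centroid there, so that unevenly spaced vertices do not bias
#' the result the way a raw vertex mean would.
#'
#' @inheritParams fit_endplate_plane
#' @return 3-D centroid (mm).
#' @export
contour_centroid <- function(points, level = NULL) {
  points <- as.matrix(points)
  pl <- fit_endplate_plane(points, level)
  basis <- plane_basis(pl$normal)
  uv <- sweep(points, 2, pl$point) %*% basis
  u <- uv[, 1]; v <- uv[, 2]
  u2 <- c(u[-1], u[1]); v2 <- c(v[-1], v[1])
  cross <- u * v2 - u2 * v
  area2 <- sum(cross)
  if (abs(area2) < 1e-9) {
    stop("degenerate geometry", level_tag(level), ": zero-area contour", call. = FALSE)
  }
  cu <- sum((u + u2) * cross) / (3 * area2)
  cv <- sum((v + v2) * cross) / (3 * area2)
  as.numeric(pl$point + basis %*% c(cu, cv))
}

#' Anterior-posterior axis of an endplate
#'
#' Unit direction from the spinal-canal centroid toward the endplate centroid,
#' projected into the endplate plane. By construction it points anteriorly,
#' because the canal lies posterior to the vertebral body.
#'
#' @param endplate_centroid,canal_centroid 3-D points (mm).
#' @param plane_normal unit normal of the endplate plane.
#' @param level optional label for error messages.
#' @return unit 3-vector orthogonal to `plane_normal`.
#' @export
ap_axis <- function(endplate_centroid, canal_centroid, plane_normal, level = NULL) {
  d <- endplate_centroid - canal_centroid
  if (vnorm(d) < 1e-9) {
    stop("degenerate geometry", level_tag(level),
         ": canal and endplate centroids coincide", call. = FALSE)
  }
  d_in <- d - sum(d * plane_normal) * plane_normal
  if (vnorm(d_in) < 1e-9) {
    stop("degenerate geometry", level_tag(level),
         ": canal-centroid direction is perpendicular to the endplate plane",
         call. = FALSE)
  }
  unitize(d_in, "anterior-posterior axis")
}

#' Most anterior and most posterior contour points
#'
#' The anterior (posterior) landmark is the contour vertex with maximal
#' (minimal) scalar projection on the anterior-posterior axis. Ties are broken
#' by the lowest vertex index, which keeps the result deterministic.
#'
#' @param points contour matrix, one 3-D point per row.
#' @param axis unit anterior-posterior axis.
#' @return list with `anterior`, `posterior` (3-vectors) and the vertex
#'   indices `anterior_index`, `posterior_index`.
#' @export
extreme_points <- function(points, axis) {
  points <- as.matrix(points)
  s <- as.numeric(points %*% axis)
  ia <- which.max(s)   # which.max/min take the first index on ties
  ip <- which.min(s)
  list(
    anterior = points[ia, ], posterior = points[ip, ],
    anterior_index = ia, posterior_index = ip
  )
}

#' Axial rotation of an endplate relative to the sacral plate
#'
#' Both anterior-posterior axes are projected onto the transverse plane
#' (z component dropped) and the signed angle between them is returned in
#' degrees, in (-180, 180]. Rotation of the anterior tip toward patient-right
#' is positive.
#'
#' @param axis unit anterior-posterior axis of the endplate.
#' @param sacral_axis unit anterior-posterior axis of the sacral plate.
#' @return signed rotation in degrees.
#' @export
axial_rotation <- function(axis, sacral_axis) {
  a <- axis[1:2]
  s <- sacral_axis[1:2]
  if (vnorm(a) < 1e-6 || vnorm(s) < 1e-6) {
    stop("degenerate projection: anterior-posterior axis has no transverse component",
         call. = FALSE)
  }
  # clockwise-from-cranial (toward +x) positive
  atan2(a[1] * s[2] - a[2] * s[1], a[1] * s[1] + a[2] * s[2]) * DEG
}

# Direction of the intersection line of an endplate plane with the coronal
# plane; oriented by the (+z hemisphere) normal so angles are consistent.
coronal_tangent <- function(normal) {
  t <- c(-normal[3], 0, normal[1])   # normal x (0,1,0)
  if (vnorm(t) < 1e-9) {
    stop("degenerate projection: endplate plane is parallel to the coronal plane",
         call. = FALSE)
  }
  unitize(t, "coronal tangent")
}

#' Coronal Cobb angle between two endplates
#'
#' Each endplate contributes its medio-lateral tangent, the intersection of
#' its plane with the global coronal plane. The Cobb angle is the unsigned
#' angle between the two tangents in degrees, in `[0, 180)`.
#'
#' @param upper,lower `endplate_geometry` objects (or any list with a
#'   `plane_normal` field): superior endplate of the upper end vertebra and
#'   inferior endplate of the lower end vertebra.
#' @return Cobb angle in degrees.
#' @export
coronal_cobb <- function(upper, lower) {
  t1 <- coronal_tangent(upper$plane_normal)
  t2 <- coronal_tangent(lower$plane_normal)
  acos(min(1, max(-1, sum(t1 * t2)))) * DEG
}

# Apply a rigid transform (3x3 rotation R, offset t) to an n x 3 point matrix.
transform_points <- function(points, R, t = c(0, 0, 0)) {
  sweep(as.matrix(points) %*% t(R), 2, t, "+")
}
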