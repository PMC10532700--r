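#' Rigid 6-DOF transform
#'
#' A rigid transform is stored as a 4x4 homogeneous matrix with orthonormal
#' rotation part (det = +1) and translation in mm. By package convention,
#' registration transforms map preoperative-image coordinates into
#' postoperative-image coordinates.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length 3 (mm).
#' @return 4x4 matrix of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation part must be orthonormal with det = +1")
  m <- rbind(cbind(rotation, as.numeric(translation)), c(0, 0, 0, 1))
  structure(m, class = c("rigid_transform", "matrix", "array"))
}

#' @rdname rigid_transform
#' @param m 4x4 homogeneous matrix.
#' @export
as_rigid_transform <- function(m) {
  m <- unclass(m)
  stopifnot(all(dim(m) == c(4, 4)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of a rigid transform must be (0,0,0,1)")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @rdname rigid_transform
#' @param transform A `rigid_transform`.
#' @export
rt_rotation <- function(transform) unclass(transform)[1:3, 1:3]

#' @rdname rigid_transform
#' @export
rt_translation <- function(transform) unclass(transform)[1:3, 4]

#' Compose, invert and apply rigid transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`
#' (matrix product `a %*% b`). `rt_apply` maps an n x 3 point matrix (or a
#' length-3 point) through the transform.
#'
#' @param a,b,transform `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  as_rigid_transform(unclass(a) %*% unclass(b))
}

#' @rdname rt_compose
#' @export
rt_inverse <- function(transform) {
  r <- rt_rotation(transform)
  rigid_transform(t(r), -t(r) %*% rt_translation(transform))
}

#' @rdname rt_compose
#' @param points n x 3 matrix or length-3 vector of world mm points.
#' @export
rt_apply <- function(transform, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  out <- p %*% t(rt_rotation(transform))
  out <- sweep(out, 2, rt_translation(transform), `+`)
  if (is.matrix(points)) out else drop(out)
}

#' Rotation about an axis through a center point
#'
#' @param axis Length-3 axis (need not be unit).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @param center World point the rotation pivots about (default origin).
#' @param translation Extra translation applied after the rotation.
#' @return A [rigid_transform()].
#' @export
rt_axis_angle <- function(axis, angle_deg, center = c(0, 0, 0),
                          translation = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  rigid_transform(r, as.numeric(center - r %*% center) + translation)
}

# versor (quaternion vector part) parameterization used by the optimizer:
# p = (v1, v2, v3, tx, ty, tz), rotation about `center`.
versor_to_rotation <- function(v) {
  n2 <- sum(v^2)
  if (n2 >= 1) v <- v / sqrt(n2) * 0.999999  # keep on the unit-ball interior
  w <- sqrt(max(0, 1 - sum(v^2)))
  x <- v[1]; y <- v[2]; z <- v[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

rotation_to_versor <- function(r) {
  w <- sqrt(max(0, 1 + r[1, 1] + r[2, 2] + r[3, 3])) / 2
  if (w > 1e-6) {
    v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / (4 * w)
  } else {
    d <- diag(r)
    i <- which.max(d)
    v <- numeric(3)
    v[i] <- sqrt(max(0, 1 + 2 * d[i] - sum(d))) / 2
    j <- (i %% 3) + 1; k <- (j %% 3) + 1
    v[j] <- (r[j, i] + r[i, j]) / (4 * v[i])
    v[k] <- (r[k, i] + r[i, k]) / (4 * v[i])
  }
  if (w < 0) -v else v
}

rt_from_params <- function(p, center) {
  r <- versor_to_rotation(p[1:3])
  rigid_transform(r, as.numeric(center - r %*% center) + p[4:6])
}

rt_to_params <- function(transform, center) {
  r <- rt_rotation(transform)
  v <- rotation_to_versor(r)
  t_extra <- rt_translation(transform) - as.numeric(center - r %*% center)
  c(v, t_extra)
}

#' Angle of the rotation part of a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return Rotation magnitude in degrees.
#' @export
rt_rotation_angle <- function(transform) {
  r <- rt_rotation(transform)
  acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2))) * 180 / pi
}
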