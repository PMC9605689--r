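#' Eye pose: rigid placement of an eye in the world
#'
#' A pose maps eye-local coordinates (+z forward, +y dorsal) into the world
#' frame: `world = R(quaternion) %*% local + position`.
#'
#' @param position world-frame position of the eye origin, millimetres.
#' @param quaternion unit rotation quaternion as `c(w, x, y, z)`. Must be
#'   unit-norm within `1e-6`; it is renormalised to machine precision.
#' @return an object of class `eye_pose`.
#' @examples
#' eye_pose(c(10, 0, 0), quat_from_axis_angle(c(0, 1, 0), pi / 2))
#' @export
eye_pose <- function(position = c(0, 0, 0), quaternion = c(1, 0, 0, 0)) {
  position <- as_vec3(position, "position")
  quaternion <- as.numeric(quaternion)
  if (length(quaternion) != 4L || any(!is.finite(quaternion)))
    stopf("quaternion must be a finite 4-vector (w, x, y, z)")
  n <- sqrt(sum(quaternion^2))
  if (abs(n - 1) > 1e-6) stopf("quaternion norm %.8f is not within 1e-6 of 1", n)
  structure(list(position = position, quaternion = quaternion / n),
            class = "eye_pose")
}

#' @export
print.eye_pose <- function(x, ...) {
  cat(sprintf("<eye_pose> position (%.3g, %.3g, %.3g) mm, quaternion (%.4f, %.4f, %.4f, %.4f)\n",
              x$position[1], x$position[2], x$position[3],
              x$quaternion[1], x$quaternion[2], x$quaternion[3], x$quaternion[4]))
  invisible(x)
}

#' Quaternion from an axis and an angle
#'
#' @param axis rotation axis (any non-zero 3-vector; normalised internally).
#' @param angle rotation angle, radians.
#' @return unit quaternion `c(w, x, y, z)`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- as_vec3(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n == 0) stopf("rotation axis must be non-zero")
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a pose quaternion
#'
#' @param q unit quaternion `c(w, x, y, z)` or an `eye_pose`.
#' @return a 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  if (inherits(q, "eye_pose")) q <- q$quaternion
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Shepperd's method; used when glTF nodes carry a matrix instead of a quaternion
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# quaternion product a * b (apply b, then a)
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}
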