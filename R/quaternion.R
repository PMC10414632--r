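# Quaternion algebra (Hamilton convention, scalar-first). Orientation
# quaternions map the sensor frame into the Earth frame: v_E = q (0,v_S) q*.
# All helpers accept either a length-4 vector or an n x 4 matrix of rows.

as_quat_mat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, 1, 4)
  stopifnot(ncol(q) == 4)
  q
}

#' Normalize quaternions to unit norm
#' @param q length-4 quaternion or n x 4 matrix (scalar-first).
#' @return same shape, unit norm rows.
#' @export
quat_normalize <- function(q) {
  v <- is.null(dim(q))
  q <- as_quat_mat(q)
  n <- sqrt(rowSums(q^2))
  if (any(n == 0)) stop("cannot normalize a zero quaternion")
  q <- q / n
  if (v) q[1, ] else q
}

#' Quaternion Hamilton product
#' @param a,b quaternions (vectors or row-matched n x 4 matrices).
#' @return product a*b, same shape.
#' @export
quat_multiply <- function(a, b) {
  v <- is.null(dim(a)) && is.null(dim(b))
  a <- as_quat_mat(a); b <- as_quat_mat(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  out <- cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
  if (v) out[1, ] else out
}

#' Quaternion conjugate
#' @param q quaternion (vector or n x 4 matrix).
#' @return conjugate, same shape.
#' @export
quat_conjugate <- function(q) {
  if (is.null(dim(q))) return(c(q[1], -q[2:4]))
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rotate vectors from the sensor frame to the Earth frame
#'
#' Applies v_E = q (0, v_S) q* row-wise.
#' @param q unit quaternion(s), vector or n x 4 matrix.
#' @param v 3-vector or n x 3 matrix.
#' @return rotated vectors, same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, 1, 3)
  q <- as_quat_mat(q)
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  u <- q[, 2:4, drop = FALSE]
  w <- q[, 1]
  t2 <- cross3(u, v) + w * v
  out <- v + 2 * cross3(u, t2)
  if (vec) out[1, ] else out
}

#' Rotate vectors from the Earth frame back to the sensor frame
#' @inheritParams quat_rotate
#' @return rotated vectors, same shape as `v`.
#' @export
quat_rotate_inv <- function(q, v) quat_rotate(quat_conjugate(as_quat_mat(q)), v)

#' Quaternion from axis-angle
#' @param axis 3-vector rotation axis (normalized internally).
#' @param angle rotation angle, rad.
#' @return length-4 unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Attitude angle between two orientations
#'
#' Smallest rotation angle taking one orientation into the other,
#' sign-insensitive (q and -q are the same attitude).
#' @param qa,qb quaternions (vectors or row-matched matrices).
#' @return angle(s), rad.
#' @export
quat_angle <- function(qa, qb) {
  qa <- as_quat_mat(qa); qb <- as_quat_mat(qb)
  if (nrow(qa) == 1 && nrow(qb) > 1) qa <- qa[rep(1, nrow(qb)), , drop = FALSE]
  if (nrow(qb) == 1 && nrow(qa) > 1) qb <- qb[rep(1, nrow(qa)), , drop = FALSE]
  d <- abs(rowSums(qa * qb) /
             (sqrt(rowSums(qa^2)) * sqrt(rowSums(qb^2))))
  2 * acos(pmin(1, d))
}

#' Tilt (roll/pitch) quaternion from an accelerometer direction
#'
#' Returns the minimal rotation (zero yaw component about the measured
#' direction) that maps the measured specific-force direction onto Earth-up,
#' i.e. the initial attitude used to seed orientation estimation.
#' @param acc 3-vector accelerometer sample (sensor frame); a level
#'   stationary sensor reads (0, 0, +g).
#' @return length-4 unit quaternion (sensor -> Earth).
#' @export
quat_from_acc <- function(acc) {
  n <- sqrt(sum(acc^2))
  if (n == 0) return(c(1, 0, 0, 0))
  a <- acc / n
  z <- c(0, 0, 1)
  d <- sum(a * z)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0))  # upside down: 180 deg about x
  axis <- c(a[2] * z[3] - a[3] * z[2],
            a[3] * z[1] - a[1] * z[3],
            a[1] * z[2] - a[2] * z[1])
  quat_normalize(quat_from_axis_angle(axis, acos(d)))
}

# Body angular velocity (rad/s, sensor frame) from a quaternion track via
# omega = 2 (q* x dq/dt); central differences with sign-continuity fixup.
quat_track_to_gyro <- function(q, dt) {
  q <- as_quat_mat(q)
  n <- nrow(q)
  if (n < 3) return(matrix(0, n, 3))
  flip <- cumprod(c(1, ifelse(rowSums(q[-1, , drop = FALSE] *
                                        q[-n, , drop = FALSE]) < 0, -1, 1)))
  q <- q * flip
  dq <- rbind(q[2, ] - q[1, ],
              (q[3:n, , drop = FALSE] - q[1:(n - 2), , drop = FALSE]) / 2,
              q[n, ] - q[n - 1, ]) / dt
  w <- quat_multiply(quat_conjugate(q), dq)
  2 * w[, 2:4, drop = FALSE]
}
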