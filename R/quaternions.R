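# Unit-quaternion utilities used for segment pose representation.
# Convention: q = (w, x, y, z), scalar first; q maps segment-local vectors
# into the global frame, v_g = R(q) v_l.

#' Quaternion product
#'
#' Hamilton product of two quaternions in scalar-first convention.
#'
#' @param a,b numeric length-4 quaternions `(w, x, y, z)`.
#' @return numeric length-4 quaternion `a \%*\% b`.
#' @export
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_mul
#' @export
quat_conj <- function(a) c(a[1], -a[2], -a[3], -a[4])

quat_normalize <- function(a) a / sqrt(sum(a * a))

#' Rotation matrix from a unit quaternion
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix mapping local to global coordinates.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: picks the numerically largest pivot so the result is
#' stable for all rotations, returned with non-negative scalar part.
#'
#' @param R 3x3 rotation matrix.
#' @return unit quaternion `(w, x, y, z)`.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Quaternion for a rotation about an axis
#' @param axis length-3 axis (normalised internally).
#' @param angle rotation angle, radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotate vectors by a quaternion
#' @param q unit quaternion.
#' @param v length-3 vector or nx3 matrix of row vectors.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else as.numeric(R %*% v)
}

#' Enforce sign continuity of a quaternion time series
#'
#' Flips the sign of each quaternion so consecutive rows have positive dot
#' product (q and -q encode the same rotation; differentiation needs a
#' continuous representative).
#'
#' @param Q n x 4 matrix of unit quaternions, one row per frame.
#' @return n x 4 matrix, sign-continuous.
#' @export
quat_hemispherize <- function(Q) {
  if (nrow(Q) < 2) return(Q)
  for (i in 2:nrow(Q)) {
    if (sum(Q[i, ] * Q[i - 1, ]) < 0) Q[i, ] <- -Q[i, ]
  }
  Q
}

# Skew-symmetric (cross-product) matrix of a 3-vector: skew3(a) %*% b == a x b
skew3 <- function(a) {
  matrix(c(0, -a[3], a[2],
           a[3], 0, -a[1],
           -a[2], a[1], 0), nrow = 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
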