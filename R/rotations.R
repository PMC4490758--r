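#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices
#'
#' Right-handed rotations about the lab x, y and z axes, angle in degrees.
#'
#' @param theta Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  t <- deg2rad(theta); c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  t <- deg2rad(theta); c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  t <- deg2rad(theta); c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Test whether a matrix is a proper rotation
#'
#' @param R A 3x3 matrix.
#' @param tol Orthonormality tolerance.
#' @return Logical scalar.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (quaternion method). Uses the current
#' RNG stream.
#'
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_matrix(q)
}

#' Quaternion conversions
#'
#' Unit quaternion (w, x, y, z) to rotation matrix and back. Used for the pose
#' CSV interchange format.
#'
#' @param q Numeric length-4 unit quaternion (w, x, y, z).
#' @return `quat_to_matrix`: 3x3 rotation matrix; `matrix_to_quat`: length-4
#'   unit quaternion with non-negative scalar part.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' @rdname quat_to_matrix
#' @param R A 3x3 rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is_rotation(R, tol = 1e-6))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# 3-vector cross product
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
normalize_vec <- function(v, what = "vector", tol = 1e-8) {
  n <- sqrt(sum(v^2))
  if (n < tol) {
    stop("degenerate geometry: ", what, " has near-zero length", call. = FALSE)
  }
  v / n
}
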