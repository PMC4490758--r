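#' Total least-squares plane fit
#'
#' Fits a plane through >= 3 points by minimizing the sum of squared
#' orthogonal distances (smallest principal direction of the centred point
#' cloud). The normal can be oriented toward a reference direction.
#'
#' @param points n x 3 matrix of points (n >= 3).
#' @param orient Optional length-3 reference direction; the returned normal is
#'   flipped if needed so that `normal . orient >= 0`.
#' @return List with `point` (centroid) and `normal` (unit vector).
#' @export
fit_plane <- function(points, orient = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  d <- sv$d
  # collinear (or coincident) points: two near-zero singular values
  if (d[2] < 1e-9 * max(d[1], 1e-12)) {
    stop("fit_plane: points are collinear (degenerate plane fit)", call. = FALSE)
  }
  n <- sv$v[, 3]
  if (!is.null(orient) && sum(n * orient) < 0) n <- -n
  list(point = ctr, normal = n)
}

#' In-plane least-squares circle fit
#'
#' Projects the points onto the given plane and fits a circle by the direct
#' algebraic (Kasa) least-squares method, which is exact whenever the
#' projected points lie exactly on a circle.
#'
#' @param points n x 3 matrix (n >= 3).
#' @param plane A list with `point` and unit `normal`, e.g. from
#'   [fit_plane()].
#' @return A `circle3d` object: list with `center` (3D, on the plane),
#'   `radius` (mm) and `normal` (the plane normal).
#' @export
fit_circle_in_plane <- function(points, plane) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  n <- normalize_vec(plane$normal, "plane normal")
  # in-plane orthonormal basis
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize_vec(ref - sum(ref * n) * n, "plane basis")
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  X <- sweep(points, 2, plane$point)
  u <- X %*% e1
  v <- X %*% e2
  # Kasa fit: u^2 + v^2 = 2a u + 2b v + c, linear least squares in (a, b, c)
  A <- cbind(2 * u, 2 * v, 1)
  rhs <- u^2 + v^2
  fit <- tryCatch(qr.solve(A, rhs, tol = 1e-12),
                  error = function(e) NULL)
  if (is.null(fit)) {
    stop("fit_circle_in_plane: projected points are collinear", call. = FALSE)
  }
  a <- fit[1]; b <- fit[2]; cc <- fit[3]
  r2 <- cc + a^2 + b^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("fit_circle_in_plane: degenerate circle fit", call. = FALSE)
  }
  center <- plane$point + a * e1 + b * e2
  structure(list(center = as.numeric(center), radius = sqrt(r2), normal = n),
            class = "circle3d")
}

#' @export
print.circle3d <- function(x, ...) {
  cat("<circle3d> center (", paste(signif(x$center, 6), collapse = ", "),
      ") r =", signif(x$radius, 6), "\n")
  invisible(x)
}
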