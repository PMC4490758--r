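#' Rigid body pose
#'
#' A 6-DOF pose mapping bone (mesh) coordinates to lab coordinates:
#' `p_lab = R %*% p + t`. Lab coordinates follow the detector convention of
#' [projection_model()]: the detector plane is z = 0 and the X-ray source sits
#' on the +z axis.
#'
#' @param R 3x3 rotation matrix (or length-4 unit quaternion, w first).
#' @param t Numeric length-3 translation in mm.
#' @return An object of class `rigid_pose`.
#' @examples
#' p <- rigid_pose(rot_z(10), c(0, 0, 150))
#' apply_pose(p, c(10, 0, 0))
#' @export
rigid_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  if (is.numeric(R) && length(R) == 4) R <- quat_to_matrix(R)
  if (!is_rotation(R, tol = 1e-7)) {
    stop("rigid_pose: R is not a proper rotation matrix", call. = FALSE)
  }
  stopifnot(is.numeric(t), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("<rigid_pose> t = (", paste(signif(x$t, 5), collapse = ", "), ") mm\n")
  print(signif(x$R, 5))
  invisible(x)
}

#' Apply a rigid pose to points
#'
#' @param pose A [rigid_pose()].
#' @param points Numeric vector of length 3 or an n x 3 matrix (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_pose <- function(pose, points) {
  stopifnot(inherits(pose, "rigid_pose"))
  if (is.null(dim(points))) {
    as.numeric(pose$R %*% points + pose$t)
  } else {
    sweep(points %*% t(pose$R), 2, pose$t, "+")
  }
}

#' Compose and invert rigid poses
#'
#' `compose_pose(a, b)` is the pose that applies `b` first, then `a`.
#'
#' @param a,b,pose [rigid_pose()] objects.
#' @return A `rigid_pose`.
#' @export
compose_pose <- function(a, b) {
  rigid_pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname compose_pose
#' @export
invert_pose <- function(pose) {
  rigid_pose(t(pose$R), as.numeric(-t(pose$R) %*% pose$t))
}

#' Anatomical coordinate frame embedded in a bone
#'
#' Origin plus a right-handed orthonormal axis triad, both expressed in the
#' bone's mesh coordinates. Columns of `axes` are, in order, the
#' anteroposterior (X, anterior +), superoinferior (Y, superior +) and
#' mediolateral (Z, lateral + on a right foot) unit vectors.
#'
#' @param origin Numeric length-3 origin (mm, mesh coordinates).
#' @param axes 3x3 matrix whose columns are the X, Y, Z unit vectors.
#' @param bone Optional bone label.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axes, bone = NA_character_) {
  stopifnot(is.numeric(origin), length(origin) == 3)
  if (!is_rotation(axes, tol = 1e-9)) {
    stop("anatomical_frame: axes are not right-handed orthonormal", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), axes = axes, bone = bone),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame", if (!is.na(x$bone)) paste0(" [", x$bone, "]"), ">\n",
      sep = "")
  cat("origin (mm): ", paste(signif(x$origin, 6), collapse = ", "), "\n")
  m <- signif(x$axes, 5)
  dimnames(m) <- list(c("x", "y", "z"), c("AP(X)", "SI(Y)", "ML(Z)"))
  print(m)
  invisible(x)
}

#' Transform an anatomical frame by a rigid transform
#'
#' @param frame An [anatomical_frame()].
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation.
#' @return The transformed `anatomical_frame`.
#' @export
transform_frame <- function(frame, R, t = c(0, 0, 0)) {
  anatomical_frame(as.numeric(R %*% frame$origin + t), R %*% frame$axes,
                   bone = frame$bone)
}

#' Mirror a frame across the sagittal plane (z -> -z)
#'
#' Mirroring flips the mediolateral axis so the triad stays right-handed:
#' X and Y columns are reflected, the Z column is reflected and negated.
#' @param frame An [anatomical_frame()].
#' @return The mirrored `anatomical_frame`.
#' @export
mirror_frame <- function(frame) {
  M <- diag(c(1, 1, -1))
  axes <- M %*% frame$axes
  axes[, 3] <- -axes[, 3]
  anatomical_frame(as.numeric(M %*% frame$origin), axes, bone = frame$bone)
}
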