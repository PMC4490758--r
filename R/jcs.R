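#' Relative rotation between two anatomically framed bones
#'
#' Expresses the child bone's anatomical axes in the parent bone's anatomical
#' frame: `R_rel = t(R_parent %*% A_parent) %*% (R_child %*% A_child)` where
#' `R` are the tracked lab rotations and `A` the anatomical axis matrices.
#' For the talocrural joint the parent is the tibia and the child the talus;
#' for the subtalar joint the parent is the talus and the child the calcaneus.
#'
#' @param parent_pose,child_pose [rigid_pose()] objects (lab coordinates).
#' @param parent_frame,child_frame [anatomical_frame()] objects (mesh
#'   coordinates of the respective bones).
#' @return A 3x3 rotation matrix.
#' @export
relative_rotation <- function(parent_pose, child_pose, parent_frame, child_frame) {
  stopifnot(inherits(parent_pose, "rigid_pose"), inherits(child_pose, "rigid_pose"),
            inherits(parent_frame, "anatomical_frame"),
            inherits(child_frame, "anatomical_frame"))
  t(parent_pose$R %*% parent_frame$axes) %*% (child_pose$R %*% child_frame$axes)
}

#' Grood-Suntay decomposition of a joint rotation
#'
#' Decomposes a child-in-parent rotation into the three clinical rotation
#' components of the joint coordinate system: one body-fixed axis in the
#' parent (the mediolateral Z axis, carrying flexion), one body-fixed axis in
#' the child (the superoinferior Y axis, carrying axial rotation), and the
#' mutually perpendicular floating axis (anteroposterior, carrying
#' inversion/eversion). Algebraically this is the body-fixed Euler sequence
#' `R = Rz(alpha) %*% Rx(beta) %*% Ry(gamma)` with the frame convention
#' X = anteroposterior, Y = superoinferior, Z = mediolateral.
#'
#' Sign convention (right foot, lateral Z positive): dorsiflexion
#' `df_pf = alpha`, eversion `ev_iv = beta`, external rotation `er_ir = -gamma`,
#' so that DF, EV and ER are positive. Mirroring a trial left-right flips
#' EV/IV and ER/IR and leaves DF/PF unchanged.
#'
#' The decomposition is singular when the floating-axis angle reaches +/-90
#' degrees; poses within 1 degree of the singularity are flagged via the
#' `gimbal` attribute.
#'
#' @param R_rel 3x3 child-in-parent rotation, e.g. from [relative_rotation()].
#' @return Named numeric vector `c(df_pf, ev_iv, er_ir)` in degrees, with
#'   attribute `gimbal` (logical).
#' @seealso [gs_rotation()] for the inverse (compose) direction.
#' @examples
#' grood_suntay_angles(gs_rotation(10, 3, -2))
#' @export
grood_suntay_angles <- function(R_rel) {
  if (!is_rotation(R_rel, tol = 1e-6)) {
    stop("grood_suntay_angles: input is not a proper rotation matrix",
         call. = FALSE)
  }
  # R = Rz(a) Rx(b) Ry(g); R[3,2] = sin(b), R[1,2] = -sin(a)cos(b),
  # R[2,2] = cos(a)cos(b), R[3,1] = -cos(b)sin(g), R[3,3] = cos(b)cos(g)
  sb <- max(-1, min(1, R_rel[3, 2]))
  beta <- asin(sb)
  alpha <- atan2(-R_rel[1, 2], R_rel[2, 2])
  gamma <- atan2(-R_rel[3, 1], R_rel[3, 3])
  out <- c(df_pf = rad2deg(alpha), ev_iv = rad2deg(beta), er_ir = -rad2deg(gamma))
  attr(out, "gimbal") <- abs(rad2deg(beta)) > 89
  out
}

#' Joint rotation from Grood-Suntay angles
#'
#' Inverse of [grood_suntay_angles()]: builds the child-in-parent rotation
#' from the three clinical components (degrees, DF/EV/ER positive).
#'
#' @param df_pf,ev_iv,er_ir Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
gs_rotation <- function(df_pf, ev_iv, er_ir) {
  rot_z(df_pf) %*% rot_x(ev_iv) %*% rot_y(-er_ir)
}

#' Decompose tracked poses into joint angle series
#'
#' Applies [relative_rotation()] and [grood_suntay_angles()] frame by frame
#' for the talocrural (talus in tibia) and subtalar (calcaneus in talus)
#' joints.
#'
#' @param poses A tibble with columns `frame`, `bone` and a list-column
#'   `pose` of [rigid_pose()] objects (as stored in a trial, see
#'   [synthesize_trial()]).
#' @param frames Named list of [anatomical_frame()] objects for `tibia`,
#'   `talus`, `calcaneus`.
#' @return A tibble with columns `joint`, `frame`, `df_pf`, `ev_iv`, `er_ir`
#'   (degrees).
#' @export
decompose_poses <- function(poses, frames) {
  stopifnot(all(c("frame", "bone", "pose") %in% names(poses)),
            all(c("tibia", "talus", "calcaneus") %in% names(frames)))
  pairs <- list(
    talocrural = c(parent = "tibia", child = "talus"),
    subtalar   = c(parent = "talus", child = "calcaneus")
  )
  by_bone <- split(poses, poses$bone)
  out <- purrr::map(names(pairs), function(joint) {
    pr <- pairs[[joint]]
    pp <- by_bone[[pr[["parent"]]]]
    cp <- by_bone[[pr[["child"]]]]
    pp <- pp[order(pp$frame), ]
    cp <- cp[order(cp$frame), ]
    stopifnot(identical(pp$frame, cp$frame))
    ang <- t(vapply(seq_len(nrow(pp)), function(i) {
      grood_suntay_angles(relative_rotation(
        pp$pose[[i]], cp$pose[[i]],
        frames[[pr[["parent"]]]], frames[[pr[["child"]]]]
      ))
    }, numeric(3)))
    tibble::tibble(joint = joint, frame = pp$frame,
                   df_pf = ang[, 1], ev_iv = ang[, 2], er_ir = ang[, 3])
  })
  dplyr::bind_rows(out)
}

#' Normalize a joint angle series to stance percent
#'
#' Linearly interpolates each angle component onto a uniform 0..100 percent
#' grid between heel strike (0 %) and heel off (100 %). Endpoint values are
#' preserved exactly.
#'
#' @param series Tibble with columns `frame` and one or more angle columns
#'   (`df_pf`, `ev_iv`, `er_ir`); a `joint` column, if present, is carried
#'   through (the series must contain a single joint).
#' @param heel_strike_idx,heel_off_idx Frame indices (must exist in
#'   `series$frame`, strike strictly before off).
#' @param n_points Number of grid points, default 101 (0..100 inclusive).
#' @return Tibble with `stance_percent` and the interpolated angle columns.
#' @export
normalize_stance <- function(series, heel_strike_idx, heel_off_idx,
                             n_points = 101) {
  stopifnot(nrow(series) > 0, n_points >= 2)
  if (!all(c(heel_strike_idx, heel_off_idx) %in% series$frame)) {
    stop("normalize_stance: heel strike/off indices outside the series",
         call. = FALSE)
  }
  if (heel_strike_idx >= heel_off_idx) {
    stop("normalize_stance: heel strike must precede heel off", call. = FALSE)
  }
  if ("joint" %in% names(series) && length(unique(series$joint)) > 1) {
    stop("normalize_stance: series contains more than one joint", call. = FALSE)
  }
  keep <- series$frame >= heel_strike_idx & series$frame <= heel_off_idx
  s <- series[keep, , drop = FALSE]
  s <- s[order(s$frame), , drop = FALSE]
  pct_in <- 100 * (s$frame - heel_strike_idx) / (heel_off_idx - heel_strike_idx)
  grid <- seq(0, 100, length.out = n_points)
  comps <- intersect(c("df_pf", "ev_iv", "er_ir"), names(s))
  out <- tibble::tibble(stance_percent = grid)
  for (cc in comps) {
    out[[cc]] <- stats::approx(pct_in, s[[cc]], xout = grid, rule = 2)$y
  }
  if ("joint" %in% names(series)) {
    out <- tibble::add_column(out, joint = series$joint[[1]], .before = 1)
  }
  out
}

#' Range of motion of a joint angle series
#'
#' Per-component max minus min over the heel-strike to heel-off window
#' (the whole series when no indices are given).
#'
#' @param series Tibble with angle columns `df_pf`, `ev_iv`, `er_ir` (any
#'   subset) and optionally `frame` and `joint` columns.
#' @param heel_strike_idx,heel_off_idx Optional window (frame indices).
#' @return Tibble with columns `component` and `rom` (degrees, >= 0); a
#'   `joint` column is carried through when present.
#' @export
range_of_motion <- function(series, heel_strike_idx = NULL, heel_off_idx = NULL) {
  stopifnot(nrow(series) > 0)
  s <- series
  if (!is.null(heel_strike_idx) || !is.null(heel_off_idx)) {
    stopifnot(!is.null(heel_strike_idx), !is.null(heel_off_idx),
              "frame" %in% names(series))
    s <- s[s$frame >= heel_strike_idx & s$frame <= heel_off_idx, , drop = FALSE]
    if (nrow(s) == 0) stop("range_of_motion: empty window", call. = FALSE)
  }
  comps <- intersect(c("df_pf", "ev_iv", "er_ir"), names(s))
  stopifnot(length(comps) > 0)
  out <- tibble::tibble(
    component = comps,
    rom = unname(vapply(comps, function(cc) diff(range(s[[cc]])), numeric(1)))
  )
  if ("joint" %in% names(s)) {
    out <- tibble::add_column(out, joint = s$joint[[1]], .before = 1)
  }
  out
}
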