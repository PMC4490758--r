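#' Half-cosine stance profile
#'
#' The canonical angle-time profile used by the trial generator: a smooth
#' monotone rise from 0 to `amplitude` over normalized time `s` in [0, 1],
#' `amplitude * (1 - cos(pi * s)) / 2`. Its range over a full trial equals
#' `amplitude` exactly.
#'
#' @param s Normalized time in [0, 1].
#' @param amplitude Peak-to-peak amplitude in degrees.
#' @return Numeric vector of angles.
#' @export
half_cosine_profile <- function(s, amplitude) {
  amplitude * (1 - cos(pi * s)) / 2
}

#' Synthesize a ground-truth stance trial
#'
#' Builds per-frame rigid poses of the tibia, talus and calcaneus whose
#' joint-angle decomposition reproduces prescribed smooth angle curves.
#' Each joint/component follows a half-cosine profile scaled to the
#' subject's true range of motion, with DF, EV and ER carrying positive
#' sign. The bone poses are constructed by inverting the Grood-Suntay
#' decomposition: for each frame the child rotation is
#' `R_child = R_parent A_parent R_gs A_child^T`, with the child translated
#' so its anatomical origin keeps its neutral position relative to the
#' parent (the joint centre is the rotation pivot). The tibia holds a
#' constant lab pose; all motion lives in the joint curves, so zero ROMs
#' give a perfectly static trial.
#'
#' @param subject One-row subject record from [sample_cohort()].
#' @param bone_models A [bone_model_set()] (right-side convention).
#' @param config A [cohort_config()] (frame rate).
#' @param seed Unused by the deterministic curve construction; kept in the
#'   signature for interface stability.
#' @param lab_offset Constant lab translation applied to all bones (mm);
#'   the default centres the rearfoot in an 8-inch detector field at
#'   modest magnification.
#' @param lab_rotation Constant lab rotation of the whole limb. The default
#'   tilts the shank slightly oblique to the central ray, as a standing
#'   limb is in practice; an exactly beam-aligned limb would leave several
#'   pose degrees of freedom unobservable at first order in a single-plane
#'   silhouette, which is a degenerate (and unrealistic) imaging geometry.
#' @return A `ground_truth_trial`: list with `poses` (tibble: `frame`,
#'   `bone`, list-column `pose`), `heel_strike_idx`, `heel_off_idx`,
#'   `true_angles` (tibble: `joint`, `frame`, `df_pf`, `ev_iv`, `er_ir`),
#'   `frames` (anatomical frames used), `subject_id`, `group`.
#' @export
synthesize_trial <- function(subject, bone_models, config = cohort_config(),
                             seed = 1L, lab_offset = c(0, 8, 60),
                             lab_rotation = rot_x(10) %*% rot_y(20)) {
  stopifnot(nrow(subject) == 1, inherits(bone_models, "bone_model_set"))
  joints <- c("subtalar", "talocrural")
  comps <- c("df_pf", "ev_iv", "er_ir")
  rom_cols <- as.vector(outer(joints, comps, paste, sep = "_"))
  stopifnot(all(rom_cols %in% names(subject)))
  roms <- unlist(subject[, rom_cols])
  if (any(roms < 0)) {
    stop("synthesize_trial: subject ROMs must be non-negative", call. = FALSE)
  }
  n_frames <- round(subject$stance_ms * config$frame_rate / 1000)
  if (n_frames < 2) {
    stop("synthesize_trial: stance shorter than 2 frames", call. = FALSE)
  }
  s <- (seq_len(n_frames) - 1) / (n_frames - 1)

  frames <- build_frames(bone_models)
  tibia_pose <- rigid_pose(lab_rotation, lab_offset)

  angle_of <- function(joint) {
    a_df <- subject[[paste0(joint, "_df_pf")]]
    a_ev <- subject[[paste0(joint, "_ev_iv")]]
    a_er <- subject[[paste0(joint, "_er_ir")]]
    tibble::tibble(
      joint = joint, frame = seq_len(n_frames),
      df_pf = half_cosine_profile(s, a_df),
      ev_iv = half_cosine_profile(s, a_ev),
      er_ir = half_cosine_profile(s, a_er)
    )
  }
  tc <- angle_of("talocrural")
  st <- angle_of("subtalar")

  child_pose <- function(parent_pose, parent_frame, child_frame, ang) {
    R_gs <- gs_rotation(ang[1], ang[2], ang[3])
    R <- parent_pose$R %*% parent_frame$axes %*% R_gs %*% t(child_frame$axes)
    t <- apply_pose(parent_pose, child_frame$origin) -
      as.numeric(R %*% child_frame$origin)
    rigid_pose(R, t)
  }

  pose_rows <- purrr::map(seq_len(n_frames), function(i) {
    talus_pose <- child_pose(tibia_pose, frames$tibia, frames$talus,
                             c(tc$df_pf[i], tc$ev_iv[i], tc$er_ir[i]))
    calc_pose <- child_pose(talus_pose, frames$talus, frames$calcaneus,
                            c(st$df_pf[i], st$ev_iv[i], st$er_ir[i]))
    tibble::tibble(frame = i, bone = c("tibia", "talus", "calcaneus"),
                   pose = list(tibia_pose, talus_pose, calc_pose))
  })

  structure(list(
    poses = dplyr::bind_rows(pose_rows),
    heel_strike_idx = 1L,
    heel_off_idx = as.integer(n_frames),
    true_angles = dplyr::bind_rows(st, tc),
    frames = frames,
    subject_id = subject$subject_id,
    group = subject$group
  ), class = "ground_truth_trial")
}

#' @export
print.ground_truth_trial <- function(x, ...) {
  cat("<ground_truth_trial>", x$subject_id, paste0("(", x$group, "),"),
      x$heel_off_idx, "frames\n")
  invisible(x)
}

#' Convert trial poses to/from the CSV interchange form
#'
#' Columns: `frame`, `bone`, `qw`, `qx`, `qy`, `qz` (unit quaternion) and
#' `tx`, `ty`, `tz` (mm).
#'
#' @param poses Pose tibble with list-column `pose` (see
#'   [synthesize_trial()]).
#' @return `poses_to_table` returns a plain tibble; `table_to_poses` the
#'   list-column form.
#' @export
poses_to_table <- function(poses) {
  q <- t(vapply(poses$pose, function(p) matrix_to_quat(p$R), numeric(4)))
  tt <- t(vapply(poses$pose, function(p) p$t, numeric(3)))
  tibble::tibble(frame = poses$frame, bone = poses$bone,
                 qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
                 tx = tt[, 1], ty = tt[, 2], tz = tt[, 3])
}

#' @rdname poses_to_table
#' @param tab Tibble in the flat interchange form.
#' @export
table_to_poses <- function(tab) {
  tibble::tibble(
    frame = tab$frame, bone = tab$bone,
    pose = lapply(seq_len(nrow(tab)), function(i) {
      rigid_pose(c(tab$qw[i], tab$qx[i], tab$qy[i], tab$qz[i]),
                 c(tab$tx[i], tab$ty[i], tab$tz[i]))
    })
  )
}
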