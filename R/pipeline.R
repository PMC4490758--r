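#' Kinematic measurement of one trial
#'
#' The per-trial analysis stage: decompose bone poses into joint angles,
#' normalize to stance percent, and compute per-component ranges of motion.
#'
#' @param poses Pose tibble (`frame`, `bone`, list-column `pose`), tracked
#'   or ground truth.
#' @param frames Named list of [anatomical_frame()] objects.
#' @param heel_strike_idx,heel_off_idx Stance event frames.
#' @param n_points Stance grid size.
#' @return List with `angles` (per-frame), `normalized` (per stance
#'   percent) and `rom` (per joint/component) tibbles.
#' @export
measure_trial <- function(poses, frames, heel_strike_idx, heel_off_idx,
                          n_points = 101) {
  ang <- decompose_poses(poses, frames)
  norm <- dplyr::bind_rows(lapply(split(ang, ang$joint), normalize_stance,
                                  heel_strike_idx = heel_strike_idx,
                                  heel_off_idx = heel_off_idx,
                                  n_points = n_points))
  rom <- dplyr::bind_rows(lapply(split(ang, ang$joint), range_of_motion,
                                 heel_strike_idx = heel_strike_idx,
                                 heel_off_idx = heel_off_idx))
  list(angles = ang, normalized = norm, rom = rom)
}

#' Average stance-normalized angles into percent bins
#'
#' @param normalized Tibble from [normalize_stance()] (needs
#'   `stance_percent` plus angle columns).
#' @param n_bins Number of equal-width stance bins (default 10 x 10 %).
#' @return Tibble with `bin` (1-based), `bin_mid` (percent) and the
#'   bin-averaged angle columns.
#' @export
angle_bins <- function(normalized, n_bins = 10) {
  pct <- normalized$stance_percent
  bin <- pmin(floor(pct / (100 / n_bins)) + 1, n_bins)
  comps <- intersect(c("df_pf", "ev_iv", "er_ir"), names(normalized))
  out <- dplyr::summarise(
    dplyr::group_by(cbind(normalized, bin = bin), bin),
    dplyr::across(dplyr::all_of(comps), mean), .groups = "drop"
  )
  out$bin_mid <- (out$bin - 0.5) * (100 / n_bins)
  tibble::as_tibble(out)
}

#' Oracle-pose kinematics of a whole cohort
#'
#' Runs the simulate -> decompose -> normalize -> ROM pipeline for every
#' subject, using the ground-truth poses (no image registration) — the fast
#' statistical tier of the study.
#'
#' @param cohort Tibble from [sample_cohort()].
#' @param bone_models A [bone_model_set()] shared by the cohort (individual
#'   bone scaling does not affect joint angles).
#' @param config A [cohort_config()].
#' @return Tibble with `subject_id`, `group`, `joint`, `component`, `rom`
#'   (degrees, measured from the decomposed poses).
#' @export
cohort_kinematics <- function(cohort, bone_models = NULL,
                              config = cohort_config()) {
  if (is.null(bone_models)) bone_models <- make_bone_models(seed = config$seed)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    trial <- synthesize_trial(cohort[i, ], bone_models, config)
    meas <- measure_trial(trial$poses, trial$frames,
                          trial$heel_strike_idx, trial$heel_off_idx)
    out <- meas$rom
    out$subject_id <- cohort$subject_id[i]
    out$group <- cohort$group[i]
    out
  })
  out <- dplyr::bind_rows(rows)
  out[, c("subject_id", "group", "joint", "component", "rom")]
}

#' Parameter-recovery experiment over replicated cohorts
#'
#' Repeats the oracle-pose pipeline (cohort sampling, trial synthesis, pose
#' decomposition, ROM measurement, static-alignment measurement) over many
#' cohort replicates and compares the empirical group means of every
#' generated quantity with its configured mean, in units of the standard
#' error of the empirical mean.
#'
#' @param n_reps Number of cohort replicates.
#' @param config A [cohort_config()]; its `seed` is replaced per replicate.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @return Tibble with `measure`, `group`, `configured`, `empirical`, `sd`,
#'   `n`, `se`, `z` (standardized deviation).
#' @export
run_parameter_recovery <- function(n_reps = 200, config = cohort_config(),
                                   seed = 1L) {
  per <- vector("list", n_reps)
  bm <- make_bone_models(seed = seed)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    cohort <- sample_cohort(cfg)
    kin <- cohort_kinematics(cohort, bm, cfg)
    kin$measure <- paste(kin$joint, kin$component, sep = "_")
    stat <- measure_static_alignment(cohort, seed = seed + r)
    per[[r]] <- dplyr::bind_rows(
      kin[, c("group", "measure")] |>
        tibble::add_column(value = kin$rom),
      tibble::tibble(group = stat$group, measure = "calcaneal_pitch",
                     value = stat$calcaneal_pitch),
      tibble::tibble(group = stat$group, measure = "navicular_height_change",
                     value = stat$navicular_height_change)
    )
  }
  all <- dplyr::bind_rows(per)
  emp <- dplyr::summarise(dplyr::group_by(all, measure, group),
                          empirical = mean(value), sd = stats::sd(value),
                          n = dplyr::n(), .groups = "drop")
  cfgtab <- dplyr::bind_rows(
    tibble::tibble(measure = paste(config$rom_params$joint,
                                   config$rom_params$component, sep = "_"),
                   group = config$rom_params$group,
                   configured = config$rom_params$mean),
    tibble::tibble(measure = "calcaneal_pitch",
                   group = config$pitch_params$group,
                   configured = config$pitch_params$mean),
    tibble::tibble(measure = "navicular_height_change",
                   group = config$navdrop_params$group,
                   configured = config$navdrop_params$mean)
  )
  out <- dplyr::inner_join(cfgtab, emp, by = c("measure", "group"))
  out$se <- out$sd / sqrt(out$n)
  out$z <- (out$empirical - out$configured) / out$se
  out
}

#' Simulate stance-binned angle data for the ANOVA experiments
#'
#' Emulates measured, stance-binned joint angle curves: a shared half-cosine
#' group curve, a per-subject random level offset (between-subject
#' variability), independent per-cell measurement noise (the single-plane
#' registration precision), and optionally a group offset confined to a
#' subset of bins (a localized kinematic difference, as seen in the 20-30 %
#' window of stance).
#'
#' @param n_control,n_mtss Subjects per group.
#' @param n_bins Stance bins.
#' @param amplitude Curve amplitude in degrees (default: the control
#'   subtalar EV/IV ROM mean).
#' @param subject_sd SD of the per-subject level offset (deg).
#' @param noise_sd SD of the per-cell measurement noise (deg); the default
#'   is the reported single-plane rotation precision, 0.85 deg.
#' @param offset Group offset (deg) added to the MTSS cells in
#'   `offset_bins`; 0 gives a null (no group effect) dataset.
#' @param offset_bins Bin indices receiving the offset (default bins 3-4,
#'   i.e. 20-30 % of stance).
#' @param seed Integer seed.
#' @return Tidy tibble (`subject`, `group`, `bin`, `value`) ready for
#'   [mixed_anova()].
#' @export
simulate_binned_angles <- function(n_control = 8, n_mtss = 8, n_bins = 10,
                                   amplitude = 5.3, subject_sd = 1,
                                   noise_sd = 0.85, offset = 0,
                                   offset_bins = c(3, 4), seed = 1L) {
  with_local_seed(seed, {
    groups <- c(rep("control", n_control), rep("mtss", n_mtss))
    n <- length(groups)
    mids <- (seq_len(n_bins) - 0.5) / n_bins
    base <- half_cosine_profile(mids, amplitude)
    subj_off <- stats::rnorm(n, 0, subject_sd)
    rows <- lapply(seq_len(n), function(i) {
      mu <- base + subj_off[i]
      if (groups[i] == "mtss" && offset != 0) {
        mu[offset_bins] <- mu[offset_bins] + offset
      }
      tibble::tibble(subject = sprintf("S%03d", i), group = groups[i],
                     bin = seq_len(n_bins),
                     value = mu + stats::rnorm(n_bins, 0, noise_sd))
    })
    dplyr::bind_rows(rows)
  })
}

#' Interaction power / type-I experiments for the mixed ANOVA
#'
#' `run_interaction_power` measures how often the group x time interaction
#' detects a bin-localized group offset of the configured size;
#' `run_anova_type1` measures the interaction rejection rate with no group
#' effect (type-I calibration).
#'
#' @param n_reps Replicates.
#' @param offset Localized group offset in degrees (power experiment).
#' @param alpha Significance level.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param ... Passed to [simulate_binned_angles()].
#' @return Rejection rate (scalar in [0, 1]).
#' @export
run_interaction_power <- function(n_reps = 100, offset = 2, alpha = 0.05,
                                  seed = 1L, ...) {
  rej <- vapply(seq_len(n_reps), function(r) {
    d <- simulate_binned_angles(offset = offset, seed = seed + r, ...)
    a <- mixed_anova(d, alpha = alpha)
    a$p.value[a$term == "group:time"] < alpha
  }, logical(1))
  mean(rej)
}

#' @rdname run_interaction_power
#' @export
run_anova_type1 <- function(n_reps = 1000, alpha = 0.05, seed = 1L, ...) {
  run_interaction_power(n_reps = n_reps, offset = 0, alpha = alpha,
                        seed = seed, ...)
}

#' Write a complete synthetic study to disk
#'
#' Generates and writes the full dataset: bone meshes (ASCII PLY), landmark
#' JSON, per-subject ground-truth pose and angle CSVs, static-alignment
#' scene CSV, cohort CSV, optional rendered image sequences (PNG + JSON
#' sidecar), and a manifest listing every artifact with the seeds used.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()].
#' @param render Render image sequences (slow for large cohorts).
#' @param projection A [projection_model()] used when rendering.
#' @param force Overwrite a non-empty existing directory.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
simulate_study <- function(out_dir, config = cohort_config(), render = FALSE,
                           projection = projection_model(), force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("simulate_study: output directory exists and is not empty ",
         "(use force = TRUE)", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sample_cohort(config)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  manifest <- list(seed = config$seed,
                   n_control = config$n_control, n_mtss = config$n_mtss,
                   frame_rate = config$frame_rate,
                   subjects = list())
  scenes <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    bm_seed <- config$seed * 1000L + i
    bm <- make_bone_models(side = "right", seed = bm_seed)
    for (b in names(bm$meshes)) {
      write_ply(bm$meshes[[b]], file.path(sdir, paste0(b, ".ply")))
    }
    write_landmarks_json(bm$landmarks, file.path(sdir, "landmarks.json"))
    trial <- synthesize_trial(cohort[i, ], bm, config)
    utils::write.csv(poses_to_table(trial$poses),
                     file.path(sdir, "poses.csv"), row.names = FALSE)
    utils::write.csv(trial$true_angles,
                     file.path(sdir, "true_angles.csv"), row.names = FALSE)
    n_images <- 0L
    if (render) {
      seq <- render_trial(trial, bm, projection)
      write_image_seq(seq, file.path(sdir, "images"),
                      frame_rate = config$frame_rate)
      n_images <- length(seq$frames)
    }
    sc <- generate_static_scene(cohort[i, ], seed = bm_seed)
    scenes <- c(scenes, sc)
    manifest$subjects[[sid]] <- list(
      subject_id = sid, group = cohort$group[i], bone_seed = bm_seed,
      n_frames = trial$heel_off_idx,
      heel_strike_idx = trial$heel_strike_idx,
      heel_off_idx = trial$heel_off_idx,
      images = if (render) file.path(sid, "images") else NULL,
      n_image_frames = n_images
    )
  }
  utils::write.csv(scenes_to_table(scenes),
                   file.path(out_dir, "static_scenes.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Analyze a simulated study directory
#'
#' Runs the analysis half of the pipeline on a dataset written by
#' [simulate_study()]: pose acquisition (ground-truth oracle poses, or image
#' registration when `oracle_poses = FALSE` and images were rendered), joint
#' angle decomposition and stance normalization, static alignment measures,
#' the group summary table and the per-joint/component mixed ANOVA over
#' stance bins.
#'
#' @param data_dir Dataset directory (must contain `manifest.json`).
#' @param out_dir Optional results directory; when given, result tables are
#'   written as CSV.
#' @param oracle_poses Use stored ground-truth poses (fast tier) instead of
#'   registering the rendered images.
#' @param projection A [projection_model()] (registration tier).
#' @param n_bins Stance bins for the ANOVA.
#' @param alpha Significance level.
#' @param seed Seed for the registration optimizer.
#' @return List with `rom` (per subject), `static` (per subject), `table1`
#'   (group summary) and `anova` (per joint/component interaction tests).
#' @export
analyze_study <- function(data_dir, out_dir = NULL, oracle_poses = TRUE,
                          projection = projection_model(), n_bins = 10,
                          alpha = 0.05, seed = 1L) {
  manifest_path <- file.path(data_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("analyze_study: no manifest.json in ", data_dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (length(manifest$subjects) == 0) {
    stop("analyze_study: dataset contains no subjects", call. = FALSE)
  }
  rom_rows <- list(); bin_rows <- list()
  for (sub in manifest$subjects) {
    sid <- sub$subject_id
    sdir <- file.path(data_dir, sid)
    needed <- c("poses.csv", "landmarks.json")
    miss <- needed[!file.exists(file.path(sdir, needed))]
    if (length(miss) > 0) {
      stop("analyze_study: subject ", sid, " is missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    lm <- read_landmarks_json(file.path(sdir, "landmarks.json"))
    frames <- list(tibia = build_tibia_frame(lm),
                   talus = build_talus_frame(lm),
                   calcaneus = build_calcaneus_frame(lm))
    if (oracle_poses) {
      poses <- table_to_poses(utils::read.csv(file.path(sdir, "poses.csv")))
    } else {
      if (is.null(sub$images)) {
        stop("analyze_study: subject ", sid,
             " has no rendered images for registration", call. = FALSE)
      }
      poses <- register_subject_images(data_dir, sub, projection, seed)
    }
    meas <- measure_trial(poses, frames, sub$heel_strike_idx, sub$heel_off_idx)
    rr <- meas$rom
    rr$subject_id <- sid
    rr$group <- sub$group
    rom_rows[[sid]] <- rr
    for (j in unique(meas$normalized$joint)) {
      bb <- angle_bins(meas$normalized[meas$normalized$joint == j, ], n_bins)
      bb$joint <- j; bb$subject_id <- sid; bb$group <- sub$group
      bin_rows[[paste(sid, j)]] <- bb
    }
  }
  rom <- dplyr::bind_rows(rom_rows)
  bins <- dplyr::bind_rows(bin_rows)
  scen <- table_to_scenes(utils::read.csv(file.path(data_dir,
                                                    "static_scenes.csv")))
  grp <- vapply(manifest$subjects, function(s) s$group, character(1))
  names(grp) <- vapply(manifest$subjects, function(s) s$subject_id,
                       character(1))
  static <- dplyr::bind_rows(lapply(names(grp), function(sid) {
    tibble::tibble(
      subject_id = sid, group = grp[[sid]],
      calcaneal_pitch = calcaneal_pitch(scen[[paste0(sid, ".weight_bearing")]]),
      navicular_height_change = navicular_height_change(
        scen[[paste0(sid, ".non_weight_bearing")]],
        scen[[paste0(sid, ".weight_bearing")]])
    )
  }))
  per_subject <- dplyr::bind_rows(
    tibble::tibble(subject_id = rom$subject_id, group = rom$group,
                   measure = paste(rom$joint, rom$component, sep = "_"),
                   value = rom$rom),
    tibble::tibble(subject_id = static$subject_id, group = static$group,
                   measure = "calcaneal_pitch", value = static$calcaneal_pitch),
    tibble::tibble(subject_id = static$subject_id, group = static$group,
                   measure = "navicular_height_change",
                   value = static$navicular_height_change)
  )
  # group statistics need >= 2 subjects per group; smaller datasets still
  # run the measurement stages end-to-end
  enough <- all(table(unique(per_subject[, c("subject_id", "group")])$group) >= 2) &&
    length(unique(per_subject$group)) == 2
  table1 <- if (enough) build_table1(per_subject, alpha = alpha) else NULL
  anova_rows <- list()
  if (enough) for (j in unique(bins$joint)) {
    for (cc in c("df_pf", "ev_iv", "er_ir")) {
      d <- bins[bins$joint == j, ]
      a <- mixed_anova(tibble::tibble(subject = d$subject_id, group = d$group,
                                      bin = d$bin, value = d[[cc]]),
                       alpha = alpha)
      g <- glance(a)
      g$joint <- j; g$component <- cc
      anova_rows[[paste(j, cc)]] <- g
    }
  }
  anova <- if (enough) dplyr::bind_rows(anova_rows) else NULL
  res <- list(rom = rom, static = static, table1 = table1, anova = anova)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rom, file.path(out_dir, "rom.csv"), row.names = FALSE)
    utils::write.csv(static, file.path(out_dir, "static.csv"),
                     row.names = FALSE)
    if (enough) {
      utils::write.csv(table1, file.path(out_dir, "table1.csv"),
                       row.names = FALSE)
      utils::write.csv(anova, file.path(out_dir, "anova.csv"),
                       row.names = FALSE)
    }
  }
  res
}

# registration tier of analyze_study: track each bone through the rendered
# PNG sequence, initialized at the stored first-frame pose
register_subject_images <- function(data_dir, sub, projection, seed) {
  sdir <- file.path(data_dir, sub$subject_id)
  truth <- table_to_poses(utils::read.csv(file.path(sdir, "poses.csv")))
  img_dir <- file.path(data_dir, sub$images)
  bones <- c("tibia", "talus", "calcaneus")
  frames <- lapply(seq_len(sub$n_image_frames), function(i) {
    out <- lapply(bones, function(b) {
      png::readPNG(file.path(img_dir, sprintf("frame_%03d_%s.png", i, b)))
    })
    names(out) <- bones
    out
  })
  meshes <- stats::setNames(
    lapply(bones, function(b) read_ply(file.path(sdir, paste0(b, ".ply")))),
    bones)
  init <- stats::setNames(
    lapply(bones, function(b) truth$pose[truth$frame == 1 &
                                           truth$bone == b][[1]]),
    bones)
  track_sequence(meshes, frames, init, projection, seed = seed)
}
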