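#' Reference cohort summary statistics
#'
#' The published group summaries that parameterize the synthetic cohort:
#' per-joint, per-component range-of-motion means and SDs (degrees), static
#' alignment measures, stance duration, and the published effect-size column.
#' These are the generator defaults and the input to the in-sample
#' effect-size reproduction checks.
#'
#' @return A tibble with columns `measure`, `joint`, `component`, `unit`,
#'   `control_mean`, `control_sd`, `mtss_mean`, `mtss_sd`, `published_es`.
#' @export
table1_published <- function() {
  tibble::tribble(
    ~measure, ~joint, ~component, ~unit,
    ~control_mean, ~control_sd, ~mtss_mean, ~mtss_sd, ~published_es,
    "rom", "subtalar", "df_pf", "deg", 6.1, 0.7, 6.1, 1.2, 0.1,
    "rom", "subtalar", "ev_iv", "deg", 5.3, 0.4, 7.8, 1.3, 2.6,
    "rom", "subtalar", "er_ir", "deg", 5.5, 1.1, 9.8, 0.9, 4.2,
    "rom", "talocrural", "df_pf", "deg", 13.7, 2.2, 13.6, 2.7, 0.1,
    "rom", "talocrural", "ev_iv", "deg", 2.9, 1.0, 3.4, 2.2, 0.3,
    "rom", "talocrural", "er_ir", "deg", 3.5, 1.0, 3.7, 1.1, 0.2,
    "calcaneal_pitch", NA, NA, "deg", 20.8, 5.2, 14.3, 3.8, 1.5,
    "navicular_height_change", NA, NA, "cm", 0.7, 0.2, 0.9, 0.1, 1.4,
    "stance_time", NA, NA, "ms", 319, 9, 323, 9, NA
  )
}

#' Cohort configuration
#'
#' Holds the study conditions for the synthetic cohort generator. Defaults
#' reproduce the reference study: 8 control and 8 MTSS subjects, 60 Hz
#' cineradiography, stance durations 319 +/- 9 ms (control) and
#' 323 +/- 9 ms (MTSS), and the [table1_published()] range-of-motion,
#' calcaneal-pitch and navicular-height-change distributions.
#'
#' @param n_control,n_mtss Group sizes (>= 1; >= 2 required for the group
#'   statistics).
#' @param frame_rate Sampling rate in Hz.
#' @param stance_ms Tibble with columns `group`, `mean`, `sd` (ms).
#' @param rom_params Tibble with columns `joint`, `component`, `group`,
#'   `mean`, `sd` (degrees).
#' @param pitch_params,navdrop_params Tibbles with `group`, `mean`, `sd`
#'   (degrees / cm).
#' @param seed Integer seed used by [sample_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 8, n_mtss = 8, frame_rate = 60,
                          stance_ms = NULL, rom_params = NULL,
                          pitch_params = NULL, navdrop_params = NULL,
                          seed = 1L) {
  t1 <- table1_published()
  long_groups <- function(d) {
    dplyr::bind_rows(
      dplyr::mutate(d, group = "control", mean = d$control_mean,
                    sd = d$control_sd),
      dplyr::mutate(d, group = "mtss", mean = d$mtss_mean, sd = d$mtss_sd)
    )[, c(setdiff(names(d), c("control_mean", "control_sd", "mtss_mean",
                              "mtss_sd", "published_es", "measure", "unit")),
          "group", "mean", "sd")]
  }
  if (is.null(stance_ms)) {
    stance_ms <- long_groups(t1[t1$measure == "stance_time", ])
  }
  if (is.null(rom_params)) {
    rom_params <- long_groups(t1[t1$measure == "rom", ])
  }
  if (is.null(pitch_params)) {
    pitch_params <- long_groups(t1[t1$measure == "calcaneal_pitch", ])
  }
  if (is.null(navdrop_params)) {
    navdrop_params <- long_groups(t1[t1$measure == "navicular_height_change", ])
  }
  cfg <- structure(list(
    n_control = as.integer(n_control), n_mtss = as.integer(n_mtss),
    frame_rate = frame_rate, stance_ms = stance_ms, rom_params = rom_params,
    pitch_params = pitch_params, navdrop_params = navdrop_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_control >= 1, cfg$n_mtss >= 1, cfg$frame_rate > 0)
  for (nm in c("stance_ms", "rom_params", "pitch_params", "navdrop_params")) {
    d <- cfg[[nm]]
    if (!all(c("group", "mean", "sd") %in% names(d))) {
      stop("cohort_config: ", nm, " needs columns group, mean, sd",
           call. = FALSE)
    }
    if (any(d$sd <= 0)) {
      stop("cohort_config: all SDs must be > 0 (", nm, ")", call. = FALSE)
    }
    if (!all(c("control", "mtss") %in% d$group)) {
      stop("cohort_config: ", nm, " must cover both groups", call. = FALSE)
    }
  }
  needed <- expand.grid(joint = c("subtalar", "talocrural"),
                        component = c("df_pf", "ev_iv", "er_ir"),
                        group = c("control", "mtss"),
                        stringsAsFactors = FALSE)
  have <- with(cfg$rom_params, paste(joint, component, group))
  if (!all(with(needed, paste(joint, component, group)) %in% have)) {
    stop("cohort_config: rom_params must cover both joints x 3 components x 2 groups",
         call. = FALSE)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n_control, "control /", x$n_mtss, "MTSS,",
      x$frame_rate, "Hz, seed", x$seed, "\n")
  invisible(x)
}

#' Sample a synthetic cohort
#'
#' Draws per-subject true values (ranges of motion per joint and component,
#' stance duration, calcaneal pitch, navicular height change) from the
#' configured normal distributions. Negative range-of-motion or
#' navicular-change draws (possible but rare under the default parameters)
#' are clamped at zero, since these quantities are non-negative by
#' definition.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: `subject_id`, `group`, `side`,
#'   `stance_ms`, `calcaneal_pitch`, `navicular_height_change`, and one
#'   `<joint>_<component>` ROM column (degrees) per joint/component.
#' @examples
#' sample_cohort(cohort_config(seed = 7))
#' @export
sample_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  with_local_seed(config$seed, {
    groups <- c(rep("control", config$n_control), rep("mtss", config$n_mtss))
    n <- length(groups)
    draw <- function(params) {
      m <- params$mean[match(groups, params$group)]
      s <- params$sd[match(groups, params$group)]
      stats::rnorm(n, m, s)
    }
    out <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = groups,
      side = "right",
      stance_ms = draw(config$stance_ms),
      calcaneal_pitch = pmax(draw(config$pitch_params), 0),
      navicular_height_change = pmax(draw(config$navdrop_params), 0)
    )
    rp <- config$rom_params
    for (j in unique(rp$joint)) {
      for (cc in unique(rp$component)) {
        params <- rp[rp$joint == j & rp$component == cc, ]
        out[[paste(j, cc, sep = "_")]] <- pmax(draw(params), 0)
      }
    }
    out
  })
}

#' Lateral radiograph scene
#'
#' A 2D landmark table from a standing lateral radiograph (cm), with the
#' horizontal reference direction of the radiograph.
#'
#' @param points Named list of length-2 numeric points (cm):
#'   `navicular_tuberosity`, `calcaneus_lower_end`,
#'   `first_metatarsal_lower_end`, `inferior_border_a`, `inferior_border_b`.
#' @param stance `"weight_bearing"` or `"non_weight_bearing"`.
#' @param subject_id Subject identifier.
#' @param horizontal Length-2 horizontal reference direction (default +x).
#' @return An object of class `lateral_scene`.
#' @export
lateral_scene <- function(points, stance = c("weight_bearing",
                                             "non_weight_bearing"),
                          subject_id = NA_character_, horizontal = c(1, 0)) {
  stance <- match.arg(stance)
  req <- c("navicular_tuberosity", "calcaneus_lower_end",
           "first_metatarsal_lower_end", "inferior_border_a",
           "inferior_border_b")
  missing <- setdiff(req, names(points))
  if (length(missing) > 0) {
    stop("lateral_scene: missing point(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in req) {
    stopifnot(is.numeric(points[[nm]]), length(points[[nm]]) == 2)
  }
  if (sqrt(sum((points$calcaneus_lower_end -
                  points$first_metatarsal_lower_end)^2)) < 1e-9) {
    stop("lateral_scene: degenerate baseline (calcaneus and metatarsal ends coincide)",
         call. = FALSE)
  }
  if (sqrt(sum((points$inferior_border_a - points$inferior_border_b)^2)) < 1e-9) {
    stop("lateral_scene: inferior border points coincide", call. = FALSE)
  }
  structure(list(points = points, stance = stance, subject_id = subject_id,
                 horizontal = as.numeric(horizontal)),
            class = "lateral_scene")
}

#' @export
print.lateral_scene <- function(x, ...) {
  cat("<lateral_scene>", x$subject_id, x$stance, "\n")
  invisible(x)
}

#' Synthesize the static lateral-radiograph scenes of a subject
#'
#' Builds weight-bearing and non-weight-bearing landmark scenes whose
#' measured calcaneal pitch and navicular height change equal the subject's
#' configured values exactly (the measurement operations invert the
#' construction). The baseline (calcaneus lower end to first metatarsal
#' lower end) is placed along the horizontal; scene dimensions are jittered
#' per subject for variety.
#'
#' @param subject One-row subject record from [sample_cohort()] (needs
#'   `subject_id`, `calcaneal_pitch`, `navicular_height_change`).
#' @param seed Integer seed for the scene-geometry jitter.
#' @return List with elements `weight_bearing` and `non_weight_bearing`,
#'   each a [lateral_scene()].
#' @export
generate_static_scene <- function(subject, seed = 1L) {
  stopifnot(all(c("subject_id", "calcaneal_pitch",
                  "navicular_height_change") %in% names(subject)),
            nrow(subject) == 1)
  pitch <- subject$calcaneal_pitch
  drop <- subject$navicular_height_change
  with_local_seed(seed, {
    len <- stats::runif(1, 11, 13)          # foot baseline length, cm
    x_nav <- stats::runif(1, 3.5, 4.5)      # navicular position along foot
    h_wb <- stats::runif(1, 3.0, 4.0)       # loaded navicular height, cm
    b0 <- c(stats::runif(1, 0.3, 0.7), stats::runif(1, 0.2, 0.4))
    blen <- stats::runif(1, 2.5, 3.5)       # inferior border segment length
    border_dir <- c(cos(deg2rad(pitch)), sin(deg2rad(pitch)))
    base_pts <- function(nav_h) {
      list(
        navicular_tuberosity = c(x_nav, nav_h),
        calcaneus_lower_end = c(0, 0),
        first_metatarsal_lower_end = c(len, 0),
        inferior_border_a = b0,
        inferior_border_b = b0 + blen * border_dir
      )
    }
    list(
      weight_bearing = lateral_scene(base_pts(h_wb), "weight_bearing",
                                     subject$subject_id),
      non_weight_bearing = lateral_scene(base_pts(h_wb + drop),
                                         "non_weight_bearing",
                                         subject$subject_id)
    )
  })
}

#' Convert lateral scenes to/from the tabular CSV form
#'
#' The interchange table has columns `subject_id`, `stance`, `point_name`,
#' `x_cm`, `y_cm`.
#'
#' @param scenes A list of [lateral_scene()] objects.
#' @return `scenes_to_table` returns a tibble; `table_to_scenes` a list of
#'   `lateral_scene` objects (one per subject x stance).
#' @export
scenes_to_table <- function(scenes) {
  dplyr::bind_rows(lapply(scenes, function(sc) {
    tibble::tibble(
      subject_id = sc$subject_id, stance = sc$stance,
      point_name = names(sc$points),
      x_cm = vapply(sc$points, `[`, numeric(1), 1),
      y_cm = vapply(sc$points, `[`, numeric(1), 2)
    )
  }))
}

#' @rdname scenes_to_table
#' @param tab A tibble/data.frame in the interchange form.
#' @export
table_to_scenes <- function(tab) {
  keys <- unique(tab[, c("subject_id", "stance")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$subject_id == keys$subject_id[i] &
                 tab$stance == keys$stance[i], ]
    pts <- stats::setNames(
      lapply(seq_len(nrow(sub)), function(k) c(sub$x_cm[k], sub$y_cm[k])),
      sub$point_name
    )
    lateral_scene(pts, keys$stance[i], keys$subject_id[i])
  })
  names(out) <- paste(keys$subject_id, keys$stance, sep = ".")
  out
}
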