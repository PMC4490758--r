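#' Navicular height
#'
#' Perpendicular distance (cm) from the navicular tuberosity to the line
#' through the lower end of the calcaneus and the lower end of the first
#' metatarsal.
#'
#' @param scene A [lateral_scene()].
#' @return Non-negative height in cm.
#' @export
navicular_height <- function(scene) {
  stopifnot(inherits(scene, "lateral_scene"))
  p <- scene$points
  b <- p$first_metatarsal_lower_end - p$calcaneus_lower_end
  nb <- sqrt(sum(b^2))
  if (nb < 1e-9) stop("navicular_height: degenerate baseline", call. = FALSE)
  w <- p$navicular_tuberosity - p$calcaneus_lower_end
  unname(abs(b[1] * w[2] - b[2] * w[1]) / nb)
}

#' Navicular height change (navicular drop)
#'
#' Unloaded minus loaded navicular height, so that an arch that lowers under
#' load gives a positive value.
#'
#' @param nwb Non-weight-bearing [lateral_scene()].
#' @param wb Weight-bearing [lateral_scene()] of the same subject.
#' @return Height change in cm.
#' @export
navicular_height_change <- function(nwb, wb) {
  stopifnot(inherits(nwb, "lateral_scene"), inherits(wb, "lateral_scene"))
  if (nwb$stance != "non_weight_bearing" || wb$stance != "weight_bearing") {
    stop("navicular_height_change: scenes passed in the wrong order",
         call. = FALSE)
  }
  if (!is.na(nwb$subject_id) && !is.na(wb$subject_id) &&
      nwb$subject_id != wb$subject_id) {
    stop("navicular_height_change: scenes are from different subjects",
         call. = FALSE)
  }
  navicular_height(nwb) - navicular_height(wb)
}

#' Calcaneal pitch
#'
#' Unsigned angle (degrees, in [0, 90]) between the inferior calcaneal
#' border line and the scene's horizontal reference direction, from a
#' weight-bearing lateral radiograph.
#'
#' @param scene A [lateral_scene()].
#' @return Angle in degrees.
#' @export
calcaneal_pitch <- function(scene) {
  stopifnot(inherits(scene, "lateral_scene"))
  p <- scene$points
  b <- p$inferior_border_b - p$inferior_border_a
  if (sqrt(sum(b^2)) < 1e-9) {
    stop("calcaneal_pitch: zero-length inferior border vector", call. = FALSE)
  }
  h <- scene$horizontal
  if (sqrt(sum(h^2)) < 1e-9) {
    stop("calcaneal_pitch: zero-length horizontal reference", call. = FALSE)
  }
  cr <- abs(b[1] * h[2] - b[2] * h[1])
  dt <- abs(sum(b * h))
  unname(rad2deg(atan2(cr, dt)))
}

#' Static alignment measures for a whole cohort
#'
#' Generates the per-subject lateral scenes and measures them back, returning
#' a tidy per-subject table (the radiographic static-alignment stage of the
#' pipeline).
#'
#' @param cohort Tibble from [sample_cohort()].
#' @param seed Integer; per-subject scene seeds are derived from it.
#' @return Tibble with `subject_id`, `group`, `calcaneal_pitch`,
#'   `navicular_height_change` as measured from the scenes.
#' @export
measure_static_alignment <- function(cohort, seed = 1L) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    sc <- generate_static_scene(cohort[i, ], seed = seed + i)
    tibble::tibble(
      subject_id = cohort$subject_id[i],
      group = cohort$group[i],
      calcaneal_pitch = calcaneal_pitch(sc$weight_bearing),
      navicular_height_change = navicular_height_change(
        sc$non_weight_bearing, sc$weight_bearing)
    )
  })
  dplyr::bind_rows(rows)
}
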