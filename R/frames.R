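#' Landmark sets
#'
#' Landmarks are named 3D points in bone mesh coordinates (mm), stored as a
#' named list of length-3 numeric vectors — the in-memory form of the
#' landmark JSON interchange format (`{"name": [x, y, z], ...}`).
#'
#' Required names per bone:
#' \describe{
#'   \item{tibia}{`plafond_center`, `plafond_anterior_edge_a`,
#'     `plafond_anterior_edge_b`, `shaft_center_5cm`, `shaft_center_10cm`}
#'   \item{talus}{`trochlea_anteromedial`, `trochlea_anterolateral`,
#'     `trochlea_posteromedial`, `trochlea_posterolateral`, `trochlea_highest`}
#'   \item{calcaneus}{`middle_facet_most_lateral`,
#'     `posterior_facet_most_lateral`, `inferior_border_a`,
#'     `inferior_border_b`, `lateral_wall_a`, `lateral_wall_b`}
#' }
#'
#' @param landmarks Named list of length-3 numeric vectors.
#' @param required Character vector of required names.
#' @return `check_landmarks` returns the landmarks invisibly, erroring on a
#'   missing or malformed entry.
#' @keywords internal
check_landmarks <- function(landmarks, required) {
  missing <- setdiff(required, names(landmarks))
  if (length(missing) > 0) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in required) {
    p <- landmarks[[nm]]
    if (!is.numeric(p) || length(p) != 3 || anyNA(p)) {
      stop("landmark '", nm, "' is not a numeric 3-vector", call. = FALSE)
    }
  }
  invisible(landmarks)
}

tibia_landmark_names <- c("plafond_center", "plafond_anterior_edge_a",
                          "plafond_anterior_edge_b", "shaft_center_5cm",
                          "shaft_center_10cm")
talus_landmark_names <- c("trochlea_anteromedial", "trochlea_anterolateral",
                          "trochlea_posteromedial", "trochlea_posterolateral",
                          "trochlea_highest")
calcaneus_landmark_names <- c("middle_facet_most_lateral",
                              "posterior_facet_most_lateral",
                              "inferior_border_a", "inferior_border_b",
                              "lateral_wall_a", "lateral_wall_b")

#' Mirror a landmark set across the sagittal plane
#'
#' Negates the mediolateral (z) coordinate of every landmark; used to map
#' left-side bones to the package's right-side sign convention.
#'
#' @param landmarks Named list of length-3 numeric points.
#' @return Mirrored landmark list.
#' @export
mirror_landmarks <- function(landmarks) {
  lapply(landmarks, function(p) p * c(1, 1, -1))
}

#' Tibial anatomical frame
#'
#' Origin at the flat centre of the tibial plafond. The superoinferior (Y)
#' axis is the primary axis, running from the distal shaft centre at 5 cm to
#' the centre at 10 cm above the joint surface (superior positive). The
#' anteroposterior (X) axis is the perpendicular dropped from the origin onto
#' the anterior plafond edge line (anterior positive), re-orthogonalized
#' against Y. Z = X x Y completes the right-handed triad (lateral positive on
#' a right foot).
#'
#' @param landmarks Named landmark list (see [check_landmarks()] for names).
#' @return An [anatomical_frame()].
#' @export
build_tibia_frame <- function(landmarks) {
  check_landmarks(landmarks, tibia_landmark_names)
  o <- landmarks$plafond_center
  y <- normalize_vec(landmarks$shaft_center_10cm - landmarks$shaft_center_5cm,
                     "tibial shaft axis")
  e <- normalize_vec(landmarks$plafond_anterior_edge_b -
                       landmarks$plafond_anterior_edge_a,
                     "anterior plafond edge line")
  if (abs(sum(e * y)) > 1 - 1e-8) {
    stop("build_tibia_frame: degenerate landmarks (anterior edge line ",
         "parallel to the shaft axis)", call. = FALSE)
  }
  # perpendicular from origin to the edge line, pointing anterior
  w <- landmarks$plafond_anterior_edge_a - o
  x0 <- w - sum(w * e) * e
  x0 <- normalize_vec(x0, "anteroposterior direction (origin on edge line?)")
  x <- x0 - sum(x0 * y) * y
  x <- normalize_vec(x, "anteroposterior axis (edge line parallel to shaft?)")
  z <- cross3(x, y)
  anatomical_frame(o, cbind(x, y, z), bone = "tibia")
}

#' Talar anatomical frame
#'
#' The trochlear circle is fit in the sagittal plane spanned by the two
#' trochlear edge midpoints and the highest trochlear point (plus any surface
#' points supplied). Origin at the circle centre; Z (mediolateral, primary)
#' is the circle-plane normal, oriented lateral on a right foot; Y
#' (superoinferior) points from the origin toward the in-plane projection of
#' the highest trochlear point; X = Y x Z (anteroposterior).
#'
#' @param landmarks Named landmark list.
#' @param trochlea_surface_points Optional n x 3 matrix of additional points
#'   on the trochlear surface used in the circle fit.
#' @return An [anatomical_frame()].
#' @export
build_talus_frame <- function(landmarks, trochlea_surface_points = NULL) {
  check_landmarks(landmarks, talus_landmark_names)
  m_ant <- (landmarks$trochlea_anteromedial + landmarks$trochlea_anterolateral) / 2
  m_post <- (landmarks$trochlea_posteromedial + landmarks$trochlea_posterolateral) / 2
  h <- landmarks$trochlea_highest
  # lateral-positive sagittal-plane normal: cross(anterior-ish, superior-ish)
  n <- cross3(m_ant - m_post, h - m_post)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) {
    stop("build_talus_frame: trochlear midpoints and highest point are collinear",
         call. = FALSE)
  }
  plane <- list(point = m_post, normal = n / nn)
  pts <- rbind(m_ant, m_post, h)
  if (!is.null(trochlea_surface_points)) {
    pts <- rbind(pts, as.matrix(trochlea_surface_points))
  }
  circ <- fit_circle_in_plane(pts, plane)
  o <- circ$center
  z <- circ$normal
  yv <- h - o
  yv <- yv - sum(yv * z) * z
  y <- normalize_vec(yv, "superoinferior axis (highest point at circle centre?)")
  x <- cross3(y, z)
  anatomical_frame(o, cbind(x, y, z), bone = "talus")
}

#' Calcaneal anatomical frame
#'
#' Origin at the midpoint of the most lateral points of the middle and
#' posterior talar articular facets. X (anteroposterior, primary) runs along
#' the inferior calcaneal border (anterior positive); Y (superoinferior) is
#' the lateral-wall direction orthogonalized against X (superior positive);
#' Z = X x Y (lateral positive on a right foot).
#'
#' @param landmarks Named landmark list.
#' @return An [anatomical_frame()].
#' @export
build_calcaneus_frame <- function(landmarks) {
  check_landmarks(landmarks, calcaneus_landmark_names)
  if (sqrt(sum((landmarks$middle_facet_most_lateral -
                  landmarks$posterior_facet_most_lateral)^2)) < 1e-6) {
    stop("build_calcaneus_frame: facet landmarks coincide", call. = FALSE)
  }
  o <- (landmarks$middle_facet_most_lateral +
          landmarks$posterior_facet_most_lateral) / 2
  x <- normalize_vec(landmarks$inferior_border_b - landmarks$inferior_border_a,
                     "inferior calcaneal border")
  w <- landmarks$lateral_wall_b - landmarks$lateral_wall_a
  yv <- w - sum(w * x) * x
  y <- normalize_vec(yv, "lateral wall axis (parallel to inferior border?)")
  z <- cross3(x, y)
  anatomical_frame(o, cbind(x, y, z), bone = "calcaneus")
}

#' Build all three frames of a bone model set
#'
#' @param models A [bone_model_set()].
#' @return Named list of [anatomical_frame()] objects (`tibia`, `talus`,
#'   `calcaneus`).
#' @export
build_frames <- function(models) {
  lm <- models$landmarks
  list(
    tibia = build_tibia_frame(lm),
    talus = build_talus_frame(lm),
    calcaneus = build_calcaneus_frame(lm)
  )
}

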