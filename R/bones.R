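#' Parametric rearfoot bone model set
#'
#' Builds simplified tibia, talus and calcaneus surface meshes with all
#' frame-construction landmarks placed analytically, in one shared "CT"
#' coordinate system at a neutral anatomical position (X anterior, Y
#' superior, Z lateral for a right foot; units mm).
#'
#' Shapes are deliberately schematic stand-ins, not anatomical
#' reconstructions: the tibia is a circular-segment prism along the
#' superoinferior axis (arc anterior, flat posterior wall), the talus a
#' circular-segment prism along the mediolateral axis whose arc is the
#' trochlear circle, and the calcaneus a box. All three are convex and have
#' no continuous rotational symmetry, so every rotation degree of freedom
#' leaves a signature in a single-plane silhouette. The tibial mesh is the
#' distal shaft segment visible in a lateral ankle field; the two
#' shaft-centre landmarks are cross-section centre points at 5 and 10 cm
#' above the joint surface on the (extrapolated) shaft axis, as the frame
#' definition requires. Every other landmark lies exactly on its mesh
#' surface.
#'
#' A per-subject global size factor is drawn from a lognormal distribution
#' (`sdlog = size_jitter`) using `seed`, so repeated calls with identical
#' arguments are bitwise identical.
#'
#' @param shape_params List of size descriptors: `scale` (global multiplier,
#'   default 1), `tibia_radius`, `tibia_length`, `talus_radius`,
#'   `talus_halfwidth`, `calcaneus_halfdim` (length-3), `size_jitter`
#'   (lognormal SD of the per-subject size factor, default 0.02).
#' @param side `"right"` or `"left"`; left-side sets are the mirror image of
#'   the right-side construction across the sagittal plane.
#' @param seed Integer seed for the subject size factor.
#' @return A `bone_model_set`: list with `meshes` (named list of
#'   [rf_mesh()]), `landmarks` (named point list, shared coordinates) and
#'   `side`.
#' @examples
#' bm <- make_bone_models(side = "right", seed = 1)
#' names(bm$meshes)
#' @export
make_bone_models <- function(shape_params = list(), side = c("right", "left"),
                             seed = 1L) {
  side <- match.arg(side)
  p <- utils::modifyList(list(
    scale = 1, tibia_radius = 13, tibia_length = 70,
    talus_radius = 20, talus_halfwidth = 15,
    calcaneus_halfdim = c(40, 20, 15), size_jitter = 0.02
  ), shape_params)
  stopifnot(p$scale > 0, p$tibia_radius > 0, p$tibia_length > 0,
            p$talus_radius > 0, p$talus_halfwidth > 0,
            all(p$calcaneus_halfdim > 0), p$size_jitter >= 0)
  s <- p$scale * with_local_seed(seed, exp(stats::rnorm(1, 0, p$size_jitter)))

  deg <- function(a) a * pi / 180

  # tibia: segment prism along +y, arc anterior (x > 0), chord posterior
  rt <- p$tibia_radius
  phi_t <- seq(-90, 90, by = 15)
  poly_t <- cbind(rt * sin(deg(phi_t)), rt * cos(deg(phi_t)))  # (u=z, v=x)
  tibia <- extrude_polygon(poly_t, origin = c(0, 0, 0),
                           e1 = c(0, 0, 1), e2 = c(1, 0, 0),
                           w_range = c(0, p$tibia_length))

  # talus: segment prism along z, trochlear arc on top, flat inferior chord
  ra <- p$talus_radius
  hw <- p$talus_halfwidth
  ct <- c(5, -25, 0)
  phi_a <- seq(0, 180, by = 10)
  poly_a <- cbind(ra * cos(deg(phi_a)), ra * sin(deg(phi_a)))  # (u=x, v=y)
  talus <- extrude_polygon(poly_a, origin = ct,
                           e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                           w_range = c(-hw, hw))

  # calcaneus: box
  hd <- p$calcaneus_halfdim
  cc <- c(-10, -55, 0)
  poly_c <- cbind(c(-1, 1, 1, -1) * hd[1], c(-1, -1, 1, 1) * hd[2])
  calcaneus <- extrude_polygon(poly_c, origin = cc,
                               e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                               w_range = c(-hd[3], hd[3]))

  troch <- function(phi, z) ct + c(ra * cos(deg(phi)), ra * sin(deg(phi)), 0) +
    c(0, 0, z)
  w <- 0.8 * hw
  landmarks <- list(
    plafond_center = c(0, 0, 0),
    plafond_anterior_edge_a = c(rt * cos(deg(15)), 0, -rt * sin(deg(15))),
    plafond_anterior_edge_b = c(rt * cos(deg(15)), 0, rt * sin(deg(15))),
    shaft_center_5cm = c(0, 50, 0),
    shaft_center_10cm = c(0, 100, 0),
    trochlea_anteromedial = troch(30, -w),
    trochlea_anterolateral = troch(30, w),
    trochlea_posteromedial = troch(150, -w),
    trochlea_posterolateral = troch(150, w),
    trochlea_highest = troch(90, 0),
    middle_facet_most_lateral = cc + c(20, 15, hd[3]),
    posterior_facet_most_lateral = cc + c(-20, 15, hd[3]),
    inferior_border_a = cc + c(-0.9 * hd[1], -hd[2], 0),
    inferior_border_b = cc + c(0.9 * hd[1], -hd[2], 0),
    lateral_wall_a = cc + c(0, -15, hd[3]),
    lateral_wall_b = cc + c(0, 15, hd[3])
  )

  meshes <- list(tibia = tibia, talus = talus, calcaneus = calcaneus)
  meshes <- lapply(meshes, function(m) rf_mesh(m$vertices * s, m$faces))
  landmarks <- lapply(landmarks, function(q) q * s)

  if (side == "left") {
    meshes <- lapply(meshes, mirror_mesh)
    landmarks <- mirror_landmarks(landmarks)
  }
  structure(list(meshes = meshes, landmarks = landmarks, side = side),
            class = "bone_model_set")
}

#' @export
print.bone_model_set <- function(x, ...) {
  cat("<bone_model_set> side =", x$side, "\n")
  for (nm in names(x$meshes)) {
    cat(sprintf("  %-10s %4d vertices, %4d triangles\n", nm,
                nrow(x$meshes[[nm]]$vertices), nrow(x$meshes[[nm]]$faces)))
  }
  cat("  landmarks:", length(x$landmarks), "\n")
  invisible(x)
}

#' Landmark JSON interchange
#'
#' Writes/reads landmarks as a JSON object mapping names to `[x, y, z]`
#' points in mm.
#'
#' @param landmarks Named list of length-3 points.
#' @param path File path.
#' @return `read_landmarks_json` returns the named landmark list.
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
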