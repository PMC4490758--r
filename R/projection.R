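#' Single-plane projection model
#'
#' Perspective pinhole geometry of an image intensifier: the detector is the
#' lab plane z = 0, the X-ray point source sits at (0, 0,
#' `source_to_detector`). A lab point p projects to detector millimetre
#' coordinates `(x, y) * m(z)` with magnification
#' `m(z) = SDD / (SDD - z)`, then to pixels with the image origin at the
#' top-left, pixel centres on integer coordinates, and the image y axis
#' pointing down. Parallel projection (`m = 1`) is available as a fallback.
#'
#' @param source_to_detector Source-to-detector distance, mm (default 1000).
#' @param pixel_spacing Detector pixel pitch, mm/px.
#' @param image_size Length-2 integer (width, height) in px. The default,
#'   together with the default pixel spacing, covers an 8-inch (203 mm)
#'   square field of view.
#' @param principal_point Length-2 (col, row) of the central ray, px;
#'   defaults to the image centre.
#' @param parallel Logical; if TRUE use parallel (orthographic) projection.
#' @return An object of class `projection_model`.
#' @export
projection_model <- function(source_to_detector = 1000, pixel_spacing = 0.5,
                             image_size = c(406, 406), principal_point = NULL,
                             parallel = FALSE) {
  stopifnot(source_to_detector > 0, pixel_spacing > 0, all(image_size > 0))
  if (is.null(principal_point)) principal_point <- (image_size + 1) / 2
  if (principal_point[1] < 1 || principal_point[1] > image_size[1] ||
      principal_point[2] < 1 || principal_point[2] > image_size[2]) {
    stop("projection_model: principal point outside the image", call. = FALSE)
  }
  structure(list(source_to_detector = source_to_detector,
                 pixel_spacing = pixel_spacing,
                 image_size = as.integer(image_size),
                 principal_point = principal_point,
                 parallel = isTRUE(parallel)),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat("<projection_model> SDD", x$source_to_detector, "mm,",
      x$pixel_spacing, "mm/px,", paste(x$image_size, collapse = "x"), "px",
      if (x$parallel) "(parallel)" else "(perspective)", "\n")
  invisible(x)
}

#' Project lab points to pixel coordinates
#'
#' @param points n x 3 matrix of lab points (mm).
#' @param projection A [projection_model()].
#' @return n x 2 matrix of (col, row) pixel coordinates.
#' @export
project_points <- function(points, projection) {
  points <- rbind(points)
  sdd <- projection$source_to_detector
  if (projection$parallel) {
    m <- rep(1, nrow(points))
  } else {
    if (any(points[, 3] >= sdd - 1e-9)) {
      stop("project_points: geometry intersects the source plane",
           call. = FALSE)
    }
    m <- sdd / (sdd - points[, 3])
  }
  u <- points[, 1] * m
  v <- points[, 2] * m
  cbind(col = projection$principal_point[1] + u / projection$pixel_spacing,
        row = projection$principal_point[2] - v / projection$pixel_spacing)
}

#' Silhouette contour of a posed mesh
#'
#' Outline (px) of the perspective projection of the mesh at the given pose.
#' The package's bone meshes are convex, for which the silhouette outline is
#' exactly the convex hull of the projected vertices; that hull is what is
#' returned (closed simple polygon, counter-clockwise in pixel coordinates).
#'
#' @param mesh An [rf_mesh()] (bone/mesh coordinates, mm).
#' @param pose A [rigid_pose()] mapping mesh to lab coordinates.
#' @param projection A [projection_model()].
#' @return m x 2 matrix of (col, row) polygon vertices (not repeated at the
#'   end).
#' @export
project_silhouette <- function(mesh, pose, projection) {
  v <- apply_pose(pose, mesh$vertices)
  if (!projection$parallel) {
    if (any(v[, 3] >= projection$source_to_detector - 1e-9)) {
      stop("project_silhouette: mesh intersects the source plane",
           call. = FALSE)
    }
    if (any(v[, 3] < 0)) {
      stop("project_silhouette: mesh behind the detector plane",
           call. = FALSE)
    }
  }
  px <- project_points(v, projection)
  hull <- grDevices::chull(px)
  px[rev(hull), , drop = FALSE]  # chull is clockwise; return CCW
}

# area of a polygon given as m x 2 matrix
polygon_area <- function(poly) abs(polygon_signed_area(poly))

# rasterize a convex polygon with area (coverage) sampling: each pixel of
# the h x w result holds the fraction of its area inside the polygon,
# approximated on an ss x ss subpixel grid. ss = 1 reduces to binary
# centre sampling. Partial boundary intensities mimic the partial-volume
# response of a real detector and carry subpixel edge position.
rasterize_coverage <- function(poly, width, height, ss = 4) {
  if (ss <= 1) return(rasterize_convex(poly, width, height) * 1)
  big <- rasterize_convex(poly * ss - (ss / 2 - 0.5), width * ss, height * ss)
  blk <- rowsum(big * 1, rep(seq_len(height), each = ss))
  t(rowsum(t(blk), rep(seq_len(width), each = ss))) / ss^2
}

# rasterize a convex polygon: matrix(h x w) logical, pixel centres at
# integer (col, row); scanline fill per row
rasterize_convex <- function(poly, width, height) {
  img <- matrix(FALSE, nrow = height, ncol = width)
  ys <- poly[, 2]
  r0 <- max(1L, ceiling(min(ys)))
  r1 <- min(height, floor(max(ys)))
  if (r0 > r1) return(img)
  m <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:m, 1), 1]; y2 <- poly[c(2:m, 1), 2]
  for (r in r0:r1) {
    # edges crossing the scanline (half-open to avoid double counting)
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    xi <- x1[cross] + (r - y1[cross]) * (x2[cross] - x1[cross]) /
      (y2[cross] - y1[cross])
    c0 <- max(1L, ceiling(min(xi)))
    c1 <- min(width, floor(max(xi)))
    if (c0 <= c1) img[r, c0:c1] <- TRUE
  }
  img
}

#' Render a trial to silhouette images
#'
#' One multi-channel image per frame: each bone's silhouette is the
#' projection of its mesh at the stored pose, rendered with subpixel area
#' sampling so boundary pixels carry their coverage fraction (the
#' partial-volume response of a real detector; `supersample = 1` gives a
#' binary centre-sampled silhouette). Optional Gaussian intensity noise
#' and blur can be added on top.
#'
#' @param trial A `ground_truth_trial` from [synthesize_trial()].
#' @param bone_models A [bone_model_set()].
#' @param projection A [projection_model()].
#' @param supersample Subpixel grid factor for coverage rendering.
#' @param noise_sd Additive Gaussian intensity noise SD (image scale 0..1),
#'   default 0 (off).
#' @param blur_sigma Gaussian blur sigma in px, default 0 (off).
#' @param seed Seed for the noise draw.
#' @return An `rf_image_seq`: list with `frames` (list; each element a named
#'   list of h x w numeric matrices, one per bone), `projection`, and
#'   `pixel_spacing` metadata. Zero-frame trials give an empty sequence.
#' @export
render_trial <- function(trial, bone_models, projection = projection_model(),
                         supersample = 4, noise_sd = 0, blur_sigma = 0,
                         seed = 1L) {
  bones <- names(bone_models$meshes)
  pose_tab <- trial$poses
  frame_ids <- sort(unique(pose_tab$frame))
  w <- projection$image_size[1]
  h <- projection$image_size[2]
  render_one <- function(i) {
    out <- lapply(bones, function(b) {
      p <- pose_tab$pose[pose_tab$frame == i & pose_tab$bone == b][[1]]
      poly <- project_silhouette(bone_models$meshes[[b]], p, projection)
      if (min(poly[, 1]) < 1 || max(poly[, 1]) > w ||
          min(poly[, 2]) < 1 || max(poly[, 2]) > h) {
        stop("render_trial: bone '", b, "' outside the field of view at frame ",
             i, call. = FALSE)
      }
      img <- rasterize_coverage(poly, w, h, ss = supersample)
      if (blur_sigma > 0) {
        img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
      }
      img
    })
    names(out) <- bones
    out
  }
  frames <- lapply(frame_ids, render_one)
  if (noise_sd > 0) {
    frames <- with_local_seed(seed, {
      lapply(frames, function(fr) {
        lapply(fr, function(img) img + matrix(stats::rnorm(w * h, 0, noise_sd),
                                              h, w))
      })
    })
  }
  structure(list(frames = frames, projection = projection,
                 pixel_spacing = projection$pixel_spacing,
                 frame_ids = frame_ids),
            class = "rf_image_seq")
}

#' @export
print.rf_image_seq <- function(x, ...) {
  cat("<rf_image_seq>", length(x$frames), "frames,",
      paste(x$projection$image_size, collapse = "x"), "px\n")
  invisible(x)
}

#' Write an image sequence to PNG files with a JSON sidecar
#'
#' 16-bit grayscale PNG per frame and bone, plus a sidecar JSON carrying the
#' pixel spacing (mm/px), frame rate and source-to-detector distance.
#'
#' @param seq An `rf_image_seq` from [render_trial()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param frame_rate Acquisition rate recorded in the sidecar, Hz.
#' @return Invisibly, the sidecar path.
#' @export
write_image_seq <- function(seq, dir, prefix = "frame", frame_rate = 60) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(seq$frames)) {
    for (b in names(seq$frames[[i]])) {
      f <- file.path(dir, sprintf("%s_%03d_%s.png", prefix, i, b))
      img <- pmin(pmax(seq$frames[[i]][[b]], 0), 1)
      png::writePNG(img, f, dpi = 25.4 / seq$pixel_spacing)
      files <- c(files, basename(f))
    }
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(list(
    pixel_spacing_mm = seq$pixel_spacing,
    frame_rate_hz = frame_rate,
    source_to_detector_mm = seq$projection$source_to_detector,
    image_size_px = seq$projection$image_size,
    files = files
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
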