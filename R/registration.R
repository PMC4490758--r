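#' Edge distance field of a silhouette image
#'
#' Thresholds the image at `threshold` and builds a signed Euclidean
#' distance field of the silhouette boundary: positive outside (distance to
#' the nearest foreground pixel), negative inside (minus the distance to the
#' nearest background pixel). Its zero crossing lies halfway between the
#' boundary pixel centres, i.e. on the continuous silhouette edge to within
#' half a pixel, so sampling `|field|` along a contour measures
#' contour-to-edge distance without the inward bias of a binary edge map.
#'
#' @param image h x w numeric matrix (values ~0..1).
#' @param threshold Foreground threshold.
#' @return An `rf_distmap`: list with `d` (h x w signed distance matrix) and
#'   the image size.
#' @export
edge_distance_map <- function(image, threshold = 0.5) {
  b <- image > threshold
  if (!any(b)) stop("edge_distance_map: empty silhouette / edge map", call. = FALSE)
  h <- nrow(b); w <- ncol(b)
  d_out <- as.matrix(EBImage::distmap(EBImage::Image((!b) * 1)))  # 0 on fg
  d_in <- as.matrix(EBImage::distmap(EBImage::Image(b * 1)))      # 0 on bg
  structure(list(d = d_out - d_in, width = w, height = h),
            class = "rf_distmap")
}

# bilinear sample of the signed distance field at fractional (col, row);
# out-of-image samples are clamped to the border with the clamp distance
# added (a lower bound on the true distance that keeps the cost pulling
# back into view)
sample_distmap <- function(dm, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xc <- pmin(pmax(x, 1), dm$width)
  yc <- pmin(pmax(y, 1), dm$height)
  extra <- sqrt((x - xc)^2 + (y - yc)^2)
  x0 <- pmin(floor(xc), dm$width - 1); y0 <- pmin(floor(yc), dm$height - 1)
  fx <- xc - x0; fy <- yc - y0
  d <- dm$d
  v00 <- d[cbind(y0, x0)]; v01 <- d[cbind(y0, x0 + 1)]
  v10 <- d[cbind(y0 + 1, x0)]; v11 <- d[cbind(y0 + 1, x0 + 1)]
  abs((v00 * (1 - fx) + v01 * fx) * (1 - fy) +
        (v10 * (1 - fx) + v11 * fx) * fy) + extra
}

# bilinear intensity sample at fractional (col, row), clamped to the image
sample_bilinear <- function(img, pts) {
  w <- ncol(img); h <- nrow(img)
  x <- pmin(pmax(pts[, 1], 1), w)
  y <- pmin(pmax(pts[, 2], 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# resample a closed polygon at roughly uniform arc-length spacing (px)
resample_polygon <- function(poly, step = 0.75) {
  m <- nrow(poly)
  p2 <- poly[c(2:m, 1), , drop = FALSE]
  seglen <- sqrt(rowSums((p2 - poly)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[m + 1]
  if (total < 1e-12) return(poly[1, , drop = FALSE])
  s <- seq(0, total, by = step)
  s <- s[s < total]
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  f <- (s - cum[seg]) / pmax(seglen[seg], 1e-12)
  poly[seg, , drop = FALSE] * (1 - f) + p2[seg, , drop = FALSE] * f
}

#' Contour matching cost
#'
#' Mean distance-transform value of the image's silhouette edge map sampled
#' along the model contour: zero iff the contours coincide on the pixel
#' grid, and approximately the mean contour-to-edge distance in pixels
#' otherwise.
#'
#' @param model_contour m x 2 polygon in px, e.g. from
#'   [project_silhouette()].
#' @param image h x w numeric matrix, or a precomputed [edge_distance_map()].
#' @param step Contour resampling step in px.
#' @return Non-negative scalar cost (px).
#' @export
contour_cost <- function(model_contour, image, step = 0.75) {
  dm <- if (inherits(image, "rf_distmap")) image else edge_distance_map(image)
  pts <- resample_polygon(model_contour, step = step)
  mean(sample_distmap(dm, pts))
}

# pose perturbation used by the optimizer: lab-frame rotation about the
# model's lab centroid plus a translation, parameters (deg, deg, deg, mm x3)
perturb_pose <- function(init, centroid_mesh, x) {
  dR <- rot_z(x[3]) %*% rot_y(x[2]) %*% rot_x(x[1])
  R <- dR %*% init$R
  c0 <- apply_pose(init, centroid_mesh)
  t <- c0 + x[4:6] - as.numeric(R %*% centroid_mesh)
  rigid_pose(R, t)
}

#' Register a bone mesh to a single silhouette image
#'
#' Derivative-free 6-DOF local search (Nelder-Mead with seeded jittered
#' restarts) minimizing [contour_cost()] between the projected mesh
#' silhouette and the image's edge map. The search is local: the initial
#' pose is expected within roughly 10 degrees / 10 mm in-plane of the true
#' pose. In single-plane geometry the out-of-plane translation (along the
#' beam, z) is only weakly observable — it enters the silhouette through
#' magnification alone — so its error can be an order of magnitude larger
#' than the in-plane components; the result notes this per-DOF confidence.
#'
#' @param mesh An [rf_mesh()].
#' @param image Silhouette image matrix (this bone's channel) or a
#'   precomputed [edge_distance_map()].
#' @param init Initial [rigid_pose()].
#' @param projection A [projection_model()].
#' @param restarts Number of jittered restarts (first start is unjittered).
#' @param rot_jitter,trans_jitter Restart jitter half-widths (deg, mm).
#' @param max_iter Nelder-Mead iteration cap per start.
#' @param step Contour sampling step (px).
#' @param seed Integer seed (restart jitter), making the search
#'   deterministic.
#' @return An `rf_registration`: list with `pose`, `cost`, `iterations`,
#'   `converged`, `dof_note`.
#' @export
register_frame <- function(mesh, image, init, projection,
                           restarts = 8, rot_jitter = 4, trans_jitter = 4,
                           max_iter = 500, step = 0.75, seed = 1L) {
  dm <- if (inherits(image, "rf_distmap")) image else edge_distance_map(image)
  centroid <- colMeans(mesh$vertices)
  cost_fn <- function(x) {
    pose <- perturb_pose(init, centroid, x)
    poly <- tryCatch(project_silhouette(mesh, pose, projection),
                     error = function(e) NULL)
    if (is.null(poly)) return(1e6)
    contour_cost(poly, dm, step = step)
  }
  starts <- with_local_seed(seed, {
    c(list(rep(0, 6)),
      lapply(seq_len(max(0, restarts - 1)), function(i) {
        c(stats::runif(3, -rot_jitter, rot_jitter),
          stats::runif(2, -trans_jitter, trans_jitter), 0)
      }))
  })
  best <- NULL
  evals <- 0L
  for (s0 in starts) {
    fit <- stats::optim(s0, cost_fn, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-8))
    evals <- evals + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best restart; converged when the simplex tolerance is
  # reached or when the polish stops improving the cost by 1e-6 / moving
  # the parameters by 0.01 (deg / mm)
  prev_val <- best$value
  prev_par <- best$par
  fit <- stats::optim(best$par, cost_fn, method = "Nelder-Mead",
                      control = list(maxit = 4 * max_iter, reltol = 1e-9))
  evals <- evals + fit$counts[["function"]]
  if (fit$value < best$value) best <- fit
  converged <- fit$convergence == 0 ||
    prev_val - best$value < 1e-6 ||
    all(abs(best$par - prev_par) < 0.01)
  final_par <- best$par
  final_cost <- best$value
  # subpixel refinement on coverage-rendered (grayscale) images: at the
  # true edge the bilinear image intensity is 0.5, so minimizing the
  # |I - 0.5| residual along the contour localizes the edge below the
  # quantization floor of the thresholded distance field. Falls back to
  # the distance term for contour samples outside the boundary band.
  if (!inherits(image, "rf_distmap") &&
      any(image > 0.05 & image < 0.95)) {
    band <- 1.5
    cost_aa <- function(x) {
      pose <- perturb_pose(init, centroid, x)
      poly <- tryCatch(project_silhouette(mesh, pose, projection),
                       error = function(e) NULL)
      if (is.null(poly)) return(1e6)
      pts <- resample_polygon(poly, step = step)
      d <- sample_distmap(dm, pts)
      v <- abs(sample_bilinear(image, pts) - 0.5)
      mean(ifelse(d <= band, v, v + d - band))
    }
    aa_starts <- with_local_seed(seed + 7L, {
      c(list(final_par),
        lapply(1:2, function(i) {
          final_par + c(stats::runif(3, -1, 1), stats::runif(2, -1, 1), 0)
        }))
    })
    aa_best <- NULL
    for (s0 in aa_starts) {
      fit2 <- stats::optim(s0, cost_aa, method = "Nelder-Mead",
                           control = list(maxit = 2 * max_iter,
                                          reltol = 1e-10))
      evals <- evals + fit2$counts[["function"]]
      if (is.null(aa_best) || fit2$value < aa_best$value) aa_best <- fit2
    }
    final_par <- aa_best$par
    final_cost <- cost_fn(final_par)
    evals <- evals + 1L
  }
  best$par <- final_par
  best$value <- final_cost
  structure(list(
    pose = perturb_pose(init, centroid, best$par),
    cost = best$value,
    iterations = evals,
    converged = converged,
    dof_note = paste("in-plane DOFs (tx, ty, in-plane rotation) well",
                     "constrained; out-of-plane translation (tz) weakly",
                     "observable in single-plane geometry")
  ), class = "rf_registration")
}

#' @export
print.rf_registration <- function(x, ...) {
  cat("<rf_registration> cost", signif(x$cost, 4), "px,",
      x$iterations, "evals,", if (x$converged) "converged" else "NOT converged",
      "\n")
  invisible(x)
}

#' Track bones through an image sequence
#'
#' Registers each bone frame by frame, initializing frame t from the
#' solution at frame t-1. A frame that fails to converge is flagged in the
#' output but does not abort the sequence.
#'
#' @param meshes Named list of [rf_mesh()] objects (subset of the sequence's
#'   bone channels).
#' @param images An `rf_image_seq` from [render_trial()], or a list (frames)
#'   of named lists of image matrices.
#' @param init_poses Named list of first-frame initial [rigid_pose()]s.
#' @param projection A [projection_model()].
#' @param restarts Restarts per frame; tracking needs fewer than a cold
#'   [register_frame()] because each frame starts at the previous solution.
#' @param ... Passed to [register_frame()].
#' @return Tibble with columns `frame`, `bone`, `pose` (list), `cost`,
#'   `converged`.
#' @export
track_sequence <- function(meshes, images, init_poses, projection,
                           restarts = 3, ...) {
  frames <- if (inherits(images, "rf_image_seq")) images$frames else images
  stopifnot(all(names(meshes) %in% names(frames[[1]])),
            all(names(meshes) %in% names(init_poses)))
  out <- list()
  current <- init_poses
  for (i in seq_along(frames)) {
    for (b in names(meshes)) {
      reg <- register_frame(meshes[[b]], frames[[i]][[b]], current[[b]],
                            projection, restarts = restarts, ...)
      current[[b]] <- reg$pose
      out[[length(out) + 1]] <- tibble::tibble(
        frame = i, bone = b, pose = list(reg$pose), cost = reg$cost,
        converged = reg$converged
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Rotation angle between two poses
#'
#' Geodesic rotation distance (degrees) between the rotations of two poses;
#' a convenience for registration-accuracy reporting.
#'
#' @param a,b [rigid_pose()] objects.
#' @return Angle in degrees.
#' @export
rotation_angle_between <- function(a, b) {
  R <- a$R %*% t(b$R)
  rad2deg(acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)))
}
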