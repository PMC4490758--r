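#' Triangle mesh
#'
#' Minimal triangulated-surface container: `vertices` is an n x 3 numeric
#' matrix (mm), `faces` an m x 3 integer matrix of 1-based vertex indices
#' with consistent outward (counter-clockwise) winding.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix.
#' @return An object of class `rf_mesh`.
#' @export
rf_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "rf_mesh")
}

#' @export
print.rf_mesh <- function(x, ...) {
  cat("<rf_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles\n", sep = "")
  invisible(x)
}

#' Mesh validity checks
#'
#' `mesh_is_closed` tests that every undirected edge is shared by exactly two
#' triangles with opposite orientation (a closed, manifold, consistently
#' oriented surface). `mesh_min_triangle_area` returns the smallest triangle
#' area (mm^2), used to reject degenerate triangulations.
#'
#' @param mesh An [rf_mesh()].
#' @return Logical / numeric scalar.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' @rdname mesh_is_closed
#' @export
mesh_min_triangle_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  min(sqrt(cx^2 + cy^2 + cz^2) / 2)
}

#' @rdname mesh_is_closed
#' @details `mesh_signed_volume` is positive for a closed mesh with outward
#'   winding (divergence theorem over the triangle fan from the origin).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Mirror a mesh across the sagittal plane (z -> -z)
#'
#' Reverses triangle winding so the surface stays consistently outward
#' oriented.
#'
#' @param mesh An [rf_mesh()].
#' @return The mirrored `rf_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 3] <- -v[, 3]
  rf_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE])
}

#' Transform mesh vertices by a rigid pose
#'
#' @param mesh An [rf_mesh()].
#' @param pose A [rigid_pose()].
#' @return The transformed `rf_mesh`.
#' @export
transform_mesh <- function(mesh, pose) {
  rf_mesh(apply_pose(pose, mesh$vertices), mesh$faces)
}

# signed area of a 2D polygon (positive = counter-clockwise)
polygon_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Extrude a convex 2D polygon into a closed prism mesh
#'
#' The polygon lives in the plane spanned by `e1` (u) and `e2` (v); the prism
#' axis is `e3 = e1 x e2`. Vertices are `origin + u*e1 + v*e2 + w*e3` for
#' `w` in `w_range`. The polygon is re-ordered counter-clockwise if needed so
#' that all faces wind outward.
#'
#' @param poly m x 2 matrix of polygon vertices (convex, in order).
#' @param origin Length-3 origin of the local system.
#' @param e1,e2 Orthonormal in-plane basis vectors.
#' @param w_range Length-2 numeric range along the axis.
#' @return A closed [rf_mesh()].
#' @keywords internal
extrude_polygon <- function(poly, origin = c(0, 0, 0),
                            e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                            w_range = c(-1, 1)) {
  poly <- as.matrix(poly)
  m <- nrow(poly)
  stopifnot(m >= 3, ncol(poly) == 2, diff(w_range) > 0)
  if (polygon_signed_area(poly) < 0) poly <- poly[m:1, , drop = FALSE]
  e3 <- cross3(e1, e2)
  to3d <- function(w) {
    sweep(poly[, 1, drop = FALSE] %*% rbind(e1) +
            poly[, 2, drop = FALSE] %*% rbind(e2) + w * rbind(e3)[rep(1, m), ],
          2, origin, "+")
  }
  vb <- to3d(w_range[1])
  vt <- to3d(w_range[2])
  v <- rbind(vb, vt)
  i <- seq_len(m)
  j <- c(2:m, 1)
  sides <- rbind(cbind(i, j, m + j), cbind(i, m + j, m + i))
  top <- cbind(m + 1, m + i[-c(1, m)], m + j[-c(1, m)])
  bottom <- cbind(1, j[-c(1, m)], i[-c(1, m)])
  rf_mesh(v, rbind(sides, top, bottom))
}

# squared distance from one point to one triangle (Ericson-style projection)
point_triangle_dist2 <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sum((p - a)^2))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sum((p - b)^2))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sum((p - (a + t * ab))^2))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sum((p - c)^2))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sum((p - (a + t * ac))^2))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sum((p - (b + t * (c - b)))^2))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  sum((p - (a + v * ab + w * ac))^2)
}

#' Distance from a point to a mesh surface
#'
#' @param point Length-3 numeric.
#' @param mesh An [rf_mesh()].
#' @return Minimum Euclidean distance (mm) to any triangle.
#' @export
point_mesh_distance <- function(point, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  d2 <- vapply(seq_len(nrow(f)), function(k) {
    point_triangle_dist2(point, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
  }, numeric(1))
  sqrt(min(d2))
}

#' Read and write ASCII PLY meshes
#'
#' Minimal ASCII PLY support for the package's triangle meshes (vertex
#' x/y/z properties and triangular faces only).
#'
#' @param mesh An [rf_mesh()].
#' @param path File path.
#' @return `read_ply` returns an `rf_mesh`; `write_ply` returns `path`
#'   invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2])) {
    stop("read_ply: not an ASCII PLY file", call. = FALSE)
  }
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vlines <- lines[(hdr_end + 1):(hdr_end + nv)]
  flines <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  v <- matrix(as.numeric(unlist(strsplit(vlines, "\\s+"))), ncol = 3,
              byrow = TRUE)
  fraw <- matrix(as.integer(unlist(strsplit(flines, "\\s+"))), ncol = 4,
                 byrow = TRUE)
  stopifnot(all(fraw[, 1] == 3L))
  rf_mesh(v, fraw[, 2:4] + 1L)
}

#' Read and write ASCII STL meshes
#'
#' STL stores a triangle soup; `read_stl` merges coincident vertices back
#' into an indexed mesh.
#'
#' @param mesh An [rf_mesh()].
#' @param path File path.
#' @param name Solid name written to the file.
#' @return `read_stl` returns an `rf_mesh`; `write_stl` returns `path`
#'   invisibly.
#' @export
write_stl <- function(mesh, path, name = "rf_mesh") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  cat("solid ", name, "\n", sep = "", file = con)
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c <- v[f[k, 3], ]
    n <- cross3(b - a, c - a)
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    cat("facet normal ", paste(format(n, digits = 9), collapse = " "), "\n",
        " outer loop\n",
        "  vertex ", paste(format(a, digits = 17), collapse = " "), "\n",
        "  vertex ", paste(format(b, digits = 17), collapse = " "), "\n",
        "  vertex ", paste(format(c, digits = 17), collapse = " "), "\n",
        " endloop\nendfacet\n", sep = "", file = con)
  }
  cat("endsolid ", name, "\n", sep = "", file = con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  soup <- do.call(rbind, nums)
  stopifnot(nrow(soup) %% 3 == 0)
  key <- apply(soup, 1, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(key, uk)
  v <- soup[match(uk, key), , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  rf_mesh(v, f)
}
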