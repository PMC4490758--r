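# an axis-aligned unit cube mesh centred at `center` with edge `edge`
cube_mesh <- function(center = c(0, 0, 0), edge = 1) {
  h <- edge / 2
  poly <- cbind(c(-h, h, h, -h), c(-h, -h, h, h))
  rearfootkin:::extrude_polygon(poly, origin = center, w_range = c(-h, h))
}

test_that("projection follows pinhole magnification geometry", {
  proj <- projection_model(source_to_detector = 1000, pixel_spacing = 0.5,
                           image_size = c(400, 400))
  # point on the detector plane: magnification 1
  p0 <- project_points(cbind(10, 0, 0), proj)
  expect_equal(unname(p0[1, 1] - proj$principal_point[1]), 20)
  # halfway to the source: magnification 2
  p1 <- project_points(cbind(10, 0, 500), proj)
  expect_equal(unname(p1[1, 1] - proj$principal_point[1]), 40)
  # image y axis points down
  p2 <- project_points(cbind(0, 10, 0), proj)
  expect_lt(p2[1, 2], proj$principal_point[2])
})

test_that("cube silhouette matches the hand-computed pinhole square", {
  proj <- projection_model(source_to_detector = 1000, pixel_spacing = 0.5,
                           image_size = c(400, 400))
  edge <- 40
  # cube centred on the axis at z = 500: near face at 520 magnifies by
  # 1000/480, and dominates the hull
  pose <- rigid_pose(diag(3), c(0, 0, 500))
  poly <- project_silhouette(cube_mesh(edge = edge), pose, proj)
  expected_half <- (edge / 2) * (1000 / 480) / 0.5  # px
  expect_equal(max(poly[, 1]) - min(poly[, 1]), 2 * expected_half,
               tolerance = 1e-9)
  expect_equal(nrow(poly), 4)  # a square
  expect_equal(rearfootkin:::polygon_area(poly), (2 * expected_half)^2,
               tolerance = 1e-9)
})

test_that("moving toward the source strictly grows the silhouette", {
  proj <- projection_model()
  areas <- vapply(c(100, 200, 300, 400), function(z) {
    rearfootkin:::polygon_area(project_silhouette(
      cube_mesh(edge = 30), rigid_pose(diag(3), c(0, 0, z)), proj))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("an in-plane 90 degree rotation of a square profile is invisible", {
  proj <- projection_model()
  m <- cube_mesh(edge = 30)
  a <- project_silhouette(m, rigid_pose(diag(3), c(0, 0, 200)), proj)
  b <- project_silhouette(m, rigid_pose(rot_z(90), c(0, 0, 200)), proj)
  keyfun <- function(p) paste(sort(apply(round(p, 9), 1, paste,
                                         collapse = ",")), collapse = ";")
  expect_identical(keyfun(a), keyfun(b))
})

test_that("rendered silhouette area matches the projected polygon", {
  proj <- projection_model(image_size = c(300, 300), pixel_spacing = 0.5)
  trial <- synthesize_trial(fixture_subject(), fixture_models)
  pose <- trial$poses$pose[trial$poses$bone == "calcaneus"][[1]]
  poly <- project_silhouette(fixture_models$meshes$calcaneus, pose, proj)
  img <- rearfootkin:::rasterize_convex(poly, 300, 300)
  expect_equal(sum(img), rearfootkin:::polygon_area(poly),
               tolerance = 0.01 * rearfootkin:::polygon_area(poly))
})

test_that("detector-parallel translation shifts the silhouette centroid", {
  proj <- projection_model()
  m <- cube_mesh(edge = 30)
  k <- 7  # mm
  z <- 200
  a <- project_silhouette(m, rigid_pose(diag(3), c(0, 0, z)), proj)
  b <- project_silhouette(m, rigid_pose(diag(3), c(k, 0, z)), proj)
  mag <- 1000 / (1000 - (z + 15))  # hull is the near face of the cube
  shift <- mean(b[, 1]) - mean(a[, 1])
  expect_equal(shift, k * mag / proj$pixel_spacing, tolerance = 1e-6)
})

test_that("rendering guards the field of view and empty trials", {
  proj <- projection_model(image_size = c(60, 60), pixel_spacing = 0.5)
  trial <- synthesize_trial(fixture_subject(), fixture_models)
  expect_error(render_trial(trial, fixture_models, proj),
               "outside the field of view")
  trial$poses <- trial$poses[0, ]
  seq0 <- render_trial(trial, fixture_models, projection_model())
  expect_length(seq0$frames, 0)
})

test_that("rendered sequences carry metadata and honour noise settings", {
  proj <- projection_model(image_size = c(300, 300), pixel_spacing = 0.7)
  subject <- fixture_subject(stance_ms = 50 + 1e-9)  # 3 frames
  trial <- synthesize_trial(subject, fixture_models)
  s0 <- render_trial(trial, fixture_models, proj)
  expect_length(s0$frames, 3)
  expect_equal(s0$pixel_spacing, 0.7)
  img <- s0$frames[[1]]$tibia
  expect_true(all(img >= 0 & img <= 1))
  expect_true(any(img > 0 & img < 1))     # coverage fractions at the edge
  expect_gt(mean(img == 1), mean(img > 0 & img < 1))  # solid interior
  # binary centre sampling agrees with coverage rendering away from edges
  s0b <- render_trial(trial, fixture_models, proj, supersample = 1)
  expect_true(all(s0b$frames[[1]]$tibia %in% c(0, 1)))
  expect_lt(mean(abs(s0b$frames[[1]]$tibia - img)), 0.01)
  s1 <- render_trial(trial, fixture_models, proj, noise_sd = 0.05, seed = 2)
  s2 <- render_trial(trial, fixture_models, proj, noise_sd = 0.05, seed = 2)
  expect_identical(s1$frames, s2$frames)  # seeded noise is reproducible
  expect_gt(stats::sd(s1$frames[[1]]$tibia - s0$frames[[1]]$tibia), 0.01)
})

test_that("source-plane intersection and bad models are rejected", {
  proj <- projection_model()
  expect_error(project_silhouette(cube_mesh(edge = 30),
                                  rigid_pose(diag(3), c(0, 0, 999)), proj),
               "source plane")
  expect_error(projection_model(pixel_spacing = 0),
               "pixel_spacing")
  expect_error(projection_model(principal_point = c(-5, 10)), "principal")
})
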