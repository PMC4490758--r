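test_that("single-axis rotations decompose to single components", {
  expect_equal(unclass(grood_suntay_angles(diag(3))),
               c(df_pf = 0, ev_iv = 0, er_ir = 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  a <- grood_suntay_angles(rot_z(10))  # parent mediolateral axis
  expect_equal(unname(a["df_pf"]), 10, tolerance = 1e-9)
  expect_equal(unname(a["ev_iv"]), 0, tolerance = 1e-9)
  expect_equal(unname(a["er_ir"]), 0, tolerance = 1e-9)
})

test_that("compose/decompose round-trips 1000 random triples exactly", {
  set.seed(3)
  worst <- 0
  for (i in 1:1000) {
    ang <- stats::runif(3, -45, 45)
    rec <- grood_suntay_angles(gs_rotation(ang[1], ang[2], ang[3]))
    worst <- max(worst, max(abs(unclass(rec) - ang)))
  }
  expect_lt(worst, 1e-9)
})

test_that("relative rotation matches the direct composition oracle", {
  set.seed(5)
  for (i in 1:20) {
    pp <- rigid_pose(random_rotation(), stats::runif(3, -10, 10))
    cp <- rigid_pose(random_rotation(), stats::runif(3, -10, 10))
    fp <- anatomical_frame(stats::runif(3), random_rotation())
    fc <- anatomical_frame(stats::runif(3), random_rotation())
    oracle <- t(pp$R %*% fp$axes) %*% (cp$R %*% fc$axes)
    expect_lt(max(abs(relative_rotation(pp, cp, fp, fc) - oracle)), 1e-12)
  }
})

test_that("joint angles are invariant to a global lab transform", {
  set.seed(6)
  worst <- 0
  for (i in 1:50) {
    pp <- rigid_pose(random_rotation(), stats::runif(3, -10, 10))
    cp <- rigid_pose(random_rotation(), stats::runif(3, -10, 10))
    fp <- anatomical_frame(c(0, 0, 0), random_rotation())
    fc <- anatomical_frame(c(0, 0, 0), random_rotation())
    g <- rigid_pose(random_rotation(), stats::runif(3, -100, 100))
    a0 <- grood_suntay_angles(relative_rotation(pp, cp, fp, fc))
    a1 <- grood_suntay_angles(relative_rotation(
      compose_pose(g, pp), compose_pose(g, cp), fp, fc))
    worst <- max(worst, max(abs(unclass(a0) - unclass(a1))))
  }
  expect_lt(worst, 1e-9)
})

test_that("mirroring flips EV/IV and ER/IR but not DF/PF", {
  M <- diag(c(1, 1, -1))
  set.seed(8)
  for (i in 1:50) {
    ang <- stats::runif(3, -40, 40)
    R <- gs_rotation(ang[1], ang[2], ang[3])
    am <- grood_suntay_angles(M %*% R %*% M)
    expect_equal(unname(am["df_pf"]), ang[1], tolerance = 1e-9)
    expect_equal(unname(am["ev_iv"]), -ang[2], tolerance = 1e-9)
    expect_equal(unname(am["er_ir"]), -ang[3], tolerance = 1e-9)
  }
})

test_that("gimbal proximity is flagged", {
  near <- grood_suntay_angles(gs_rotation(5, 89.5, -3))
  expect_true(attr(near, "gimbal"))
  far <- grood_suntay_angles(gs_rotation(5, 30, -3))
  expect_false(attr(far, "gimbal"))
})

test_that("non-rotation input is rejected", {
  expect_error(grood_suntay_angles(matrix(1, 3, 3)), "rotation")
  expect_error(rigid_pose(matrix(1, 3, 3)), "rotation")
})

test_that("stance normalization preserves endpoints and shape", {
  s <- tibble::tibble(frame = 1:11, df_pf = seq(0, 10, 1),
                      ev_iv = 5, er_ir = -2)
  n <- normalize_stance(s, 1, 11)
  expect_equal(n$stance_percent, seq(0, 100, 1))
  expect_equal(n$ev_iv, rep(5, 101))
  expect_equal(n$df_pf[c(1, 51, 101)], c(0, 5, 10), tolerance = 1e-12)

  # dense half-cosine: resampled ROM matches the analytic amplitude
  f <- 1:200
  d <- tibble::tibble(frame = f,
                      df_pf = half_cosine_profile((f - 1) / 199, 7.8),
                      ev_iv = 0, er_ir = 0)
  nn <- normalize_stance(d, 1, 200)
  expect_equal(diff(range(nn$df_pf)), 7.8, tolerance = 0.01)
})

test_that("stance normalization rejects bad indices", {
  s <- tibble::tibble(frame = 1:5, df_pf = 1:5)
  expect_error(normalize_stance(s, 3, 3), "precede")
  expect_error(normalize_stance(s, 1, 9), "outside")
})

test_that("range of motion is max minus min per component", {
  s <- tibble::tibble(joint = "subtalar", frame = 1:10, df_pf = 3,
                      ev_iv = half_cosine_profile((0:9) / 9, 6.2),
                      er_ir = -(1:10))
  r <- range_of_motion(s)
  expect_equal(r$rom[r$component == "df_pf"], 0)
  expect_equal(r$rom[r$component == "ev_iv"], 6.2, tolerance = 1e-12)
  expect_equal(r$rom[r$component == "er_ir"], 9)
  expect_error(range_of_motion(s, 11, 12), "empty")
})
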