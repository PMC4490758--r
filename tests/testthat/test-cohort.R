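test_that("default configuration reproduces the reference group summaries", {
  cfg <- cohort_config()
  t1 <- table1_published()
  sub_ev <- cfg$rom_params[cfg$rom_params$joint == "subtalar" &
                             cfg$rom_params$component == "ev_iv", ]
  expect_equal(sub_ev$mean[sub_ev$group == "control"], 5.3)
  expect_equal(sub_ev$sd[sub_ev$group == "mtss"], 1.3)
  expect_equal(cfg$pitch_params$mean, c(20.8, 14.3))
  expect_equal(cfg$navdrop_params$mean, c(0.7, 0.9))
  expect_equal(cfg$stance_ms$mean, c(319, 323))
  expect_equal(cfg$n_control, 8L)
  expect_equal(cfg$n_mtss, 8L)
  expect_equal(nrow(t1[t1$measure == "rom", ]), 6)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_control = 0))
  expect_error(cohort_config(frame_rate = 0))
  bad <- cohort_config()
  bad$rom_params$sd[1] <- 0
  expect_error(rearfootkin:::validate_cohort_config(bad), "SD")
})

test_that("cohort sampling is reproducible and has the right sizes", {
  cfg <- cohort_config(seed = 5)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$group == "control"), 8)
  expect_equal(sum(a$group == "mtss"), 8)
  c2 <- sample_cohort(cohort_config(n_control = 3, n_mtss = 5, seed = 5))
  expect_equal(table(c2$group), table(c(rep("control", 3), rep("mtss", 5))),
               ignore_attr = TRUE)
})

test_that("degenerate SDs collapse the cohort onto the configured means", {
  cfg <- cohort_config(seed = 2)
  for (nm in c("stance_ms", "rom_params", "pitch_params", "navdrop_params")) {
    cfg[[nm]]$sd <- 1e-9
  }
  coh <- sample_cohort(cfg)
  expect_equal(coh$subtalar_er_ir[coh$group == "mtss"], rep(9.8, 8),
               tolerance = 1e-6)
  expect_equal(coh$calcaneal_pitch[coh$group == "control"], rep(20.8, 8),
               tolerance = 1e-6)
})

test_that("cohort group means approach the configured values", {
  # 100 replicate cohorts; each empirical group mean within 2 SE
  cfg <- cohort_config()
  vals <- vapply(1:100, function(r) {
    cfg$seed <- 100L + r
    coh <- sample_cohort(cfg)
    mean(coh$subtalar_er_ir[coh$group == "mtss"])
  }, numeric(1))
  se <- 0.9 / sqrt(100 * 8)
  expect_lt(abs(mean(vals) - 9.8), 2 * se)
})

test_that("static scenes invert to the configured subject values", {
  set.seed(10)
  worst_p <- 0; worst_n <- 0
  for (i in 1:100) {
    subject <- tibble::tibble(subject_id = sprintf("R%03d", i),
                              calcaneal_pitch = stats::runif(1, 5, 35),
                              navicular_height_change = stats::runif(1, 0, 1.5))
    sc <- generate_static_scene(subject, seed = i)
    worst_p <- max(worst_p, abs(calcaneal_pitch(sc$weight_bearing) -
                                  subject$calcaneal_pitch))
    worst_n <- max(worst_n,
                   abs(navicular_height_change(sc$non_weight_bearing,
                                               sc$weight_bearing) -
                         subject$navicular_height_change))
  }
  expect_lt(worst_p, 1e-6)
  expect_lt(worst_n, 1e-6)
})

test_that("zero navicular change gives equal heights in both stances", {
  subject <- tibble::tibble(subject_id = "Z", calcaneal_pitch = 18,
                            navicular_height_change = 0)
  sc <- generate_static_scene(subject, seed = 3)
  expect_equal(navicular_height(sc$weight_bearing),
               navicular_height(sc$non_weight_bearing), tolerance = 1e-12)
})

test_that("scene tables round-trip through the CSV form", {
  subject <- tibble::tibble(subject_id = "S01", calcaneal_pitch = 21,
                            navicular_height_change = 0.6)
  sc <- generate_static_scene(subject, seed = 1)
  tab <- scenes_to_table(sc)
  expect_named(tab, c("subject_id", "stance", "point_name", "x_cm", "y_cm"))
  back <- table_to_scenes(tab)
  expect_equal(calcaneal_pitch(back$S01.weight_bearing),
               calcaneal_pitch(sc$weight_bearing), tolerance = 1e-12)
  expect_equal(navicular_height(back$S01.non_weight_bearing),
               navicular_height(sc$non_weight_bearing), tolerance = 1e-12)
})
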