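# build a sample with exactly the requested mean and SD
moment_matched <- function(n, m, s) {
  x <- stats::rnorm(n)
  m + s * (x - mean(x)) / stats::sd(x)
}

test_that("summary t test matches a moment-matched raw-sample oracle", {
  set.seed(14)
  for (i in 1:20) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    m1 <- stats::runif(1, -5, 5); m2 <- stats::runif(1, -5, 5)
    s1 <- stats::runif(1, 0.2, 3); s2 <- stats::runif(1, 0.2, 3)
    x <- moment_matched(n1, m1, s1); y <- moment_matched(n2, m2, s2)
    cmp <- unpaired_t_from_summary(m1, s1, n1, m2, s2, n2)
    tt <- stats::t.test(y, x, var.equal = TRUE)
    expect_equal(cmp$t0, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(cmp$p, tt$p.value, tolerance = 1e-9)
    expect_equal(c(cmp$ci_lower, cmp$ci_upper), as.numeric(tt$conf.int),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("degenerate summary inputs follow the documented conventions", {
  z <- unpaired_t_from_summary(3, 1, 8, 3, 1, 8)
  expect_equal(z$t0, 0)
  expect_equal(z$p, 1)
  same <- unpaired_t_from_summary(2, 0, 5, 2, 0, 5)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_from_summary(2, 0, 5, 3, 0, 5), "zero pooled")
  expect_error(unpaired_t_from_summary(2, 1, 1, 3, 1, 5))
})

test_that("effect size equals Cohen's d with pooled SD", {
  expect_equal(effect_size(0, 8, 8), 0)
  set.seed(15)
  for (i in 1:1000) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    m1 <- stats::runif(1, -5, 5); m2 <- stats::runif(1, -5, 5)
    s1 <- stats::runif(1, 0.2, 3); s2 <- stats::runif(1, 0.2, 3)
    cmp <- unpaired_t_from_summary(m1, s1, n1, m2, s2, n2)
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    expect_equal(cmp$es, abs(m2 - m1) / sp, tolerance = 1e-9)
  }
})

test_that("mixed ANOVA matches a hand-computed sums-of-squares oracle", {
  # balanced 2 groups x 2 subjects x 2 bins, worked by hand from the
  # mixed-model decomposition (between: group vs subject-within-group;
  # within: bin and group:bin vs subject:bin residual)
  d <- tibble::tibble(
    subject = rep(c("a", "b", "c", "d"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    bin = rep(1:2, 4),
    value = c(1, 2, 2, 4, 5, 9, 6, 12)
  )
  wide <- matrix(d$value, ncol = 2, byrow = TRUE)  # subjects x bins
  grand <- mean(d$value)
  subj_m <- rowMeans(wide)
  grp <- c("g1", "g1", "g2", "g2")
  grp_m <- tapply(subj_m, grp, mean)[grp]
  bin_m <- colMeans(wide)
  ss_group <- 2 * 2 * sum((tapply(subj_m, grp, mean) - grand)^2)
  ss_subj <- 2 * sum((subj_m - grp_m)^2)
  ss_bin <- 4 * sum((bin_m - grand)^2)
  cell_m <- rbind(colMeans(wide[1:2, ]), colMeans(wide[3:4, ]))
  ss_int <- 2 * sum((cell_m - outer(tapply(subj_m, grp, mean), bin_m, "+") +
                       grand)^2)
  ss_tot <- sum((d$value - grand)^2)
  ss_res <- ss_tot - ss_group - ss_subj - ss_bin - ss_int
  f_group <- (ss_group / 1) / (ss_subj / 2)
  f_bin <- (ss_bin / 1) / (ss_res / 2)
  f_int <- (ss_int / 1) / (ss_res / 2)
  a <- mixed_anova(d)
  expect_equal(a$statistic[a$term == "group"], f_group, tolerance = 1e-9)
  expect_equal(a$statistic[a$term == "time"], f_bin, tolerance = 1e-9)
  expect_equal(a$statistic[a$term == "group:time"], f_int, tolerance = 1e-9)
  expect_equal(a$df1, c(1, 1, 1))
  expect_equal(a$df2, c(2, 2, 2))
})

test_that("identical groups with flat curves give no effects", {
  set.seed(16)
  d <- simulate_binned_angles(amplitude = 0, subject_sd = 1, noise_sd = 0.5,
                              offset = 0, seed = 99)
  a <- mixed_anova(d)
  expect_true(all(a$p.value > 0.01))
  expect_true(all(a$statistic < 5))
  expect_null(attr(a, "posthoc"))
})

test_that("a localized group offset is detected with per-bin comparisons", {
  d <- simulate_binned_angles(offset = 3, seed = 17)
  a <- mixed_anova(d)
  expect_lt(a$p.value[a$term == "group:time"], 0.05)
  ph <- attr(a, "posthoc")
  expect_false(is.null(ph))
  expect_equal(nrow(ph), 10)
  expect_true(all(ph$p.adjusted >= ph$p.value))
})

test_that("mixed ANOVA rejects unbalanced or missing data", {
  d <- simulate_binned_angles(seed = 1)
  expect_error(mixed_anova(d[-1, ]), "exactly one value per bin")
  d2 <- d; d2$value[3] <- NA
  expect_error(mixed_anova(d2), "missing")
  d3 <- d; d3$group <- "one"
  expect_error(mixed_anova(d3), "two groups")
})

test_that("ICC forms match the mean-squares oracle formulas", {
  set.seed(18)
  m <- matrix(stats::rnorm(48), 16, 3)  # 16 items x 3 repeats
  k <- 3; n <- 16
  a <- stats::aov(value ~ item + repeatf,
                  data = data.frame(value = as.vector(m),
                                    item = factor(rep(1:n, k)),
                                    repeatf = factor(rep(1:k, each = n))))
  ms <- summary(a)[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expect_equal(icc_repeated(m, "ICC31"), (msr - mse) / (msr + (k - 1) * mse),
               tolerance = 1e-9)
  expect_equal(icc_repeated(m, "ICC21"),
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
               tolerance = 1e-9)
  ow <- stats::aov(value ~ item,
                   data = data.frame(value = as.vector(m),
                                     item = factor(rep(1:n, k))))
  mso <- summary(ow)[[1]][, "Mean Sq"]
  expect_equal(icc_repeated(m, "ICC11"),
               (mso[1] - mso[2]) / (mso[1] + (k - 1) * mso[2]),
               tolerance = 1e-9)
})

test_that("ICC behaves at the reliability extremes", {
  item <- stats::rnorm(16, 0, 3)
  expect_equal(icc_repeated(cbind(item, item, item)), 1, tolerance = 1e-12)
  expect_warning(v <- icc_repeated(matrix(rep(c(1, 2, 3), each = 10), 10, 3)),
                 "zero between-item")
  expect_equal(v, 0)
  # variance-component construction: true ICC = 9 / (9 + 1) = 0.9
  set.seed(19)
  iccs <- vapply(1:60, function(r) {
    it <- stats::rnorm(30, 0, 3)
    icc_repeated(sapply(1:3, function(k) it + stats::rnorm(30, 0, 1)))
  }, numeric(1))
  # the single-measure estimator is slightly biased downward at n = 30, so
  # check a small absolute window around the population value
  expect_lt(abs(mean(iccs) - 0.9), 0.03)
})

test_that("the normality check calibrates and detects", {
  # exact normal quantiles: statistic near its minimum
  q <- stats::qnorm(((1:50) - 0.5) / 50)
  expect_lt(ks_normality(q, n_mc = 200, seed = 1)$statistic, 0.02)
  # null calibration: p-values of normal samples are uniform
  set.seed(20)
  ps <- vapply(1:100, function(i) {
    ks_normality(stats::rnorm(40), n_mc = 400, seed = 1000 + i)$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # power: exponential samples are rejected more than half the time
  set.seed(21)
  rej <- vapply(1:200, function(i) {
    ks_normality(stats::rexp(50), n_mc = 400, seed = 2000 + i)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
  expect_error(ks_normality(rep(1, 10)), "constant")
  # agreement with the reference Lilliefors implementation
  x <- stats::rnorm(60, 2, 3)
  expect_equal(ks_normality(x, n_mc = 100, seed = 1)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
})

test_that("two-sample KS wrapper reports distribution differences", {
  set.seed(22)
  same <- ks_two_sample(stats::rnorm(100), stats::rnorm(100))
  expect_gt(same$p.value, 0.001)
  diff <- ks_two_sample(stats::rnorm(100), stats::rnorm(100, 3))
  expect_lt(diff$p.value, 1e-6)
})

test_that("the group summary table reports and stars correctly", {
  set.seed(23)
  per <- dplyr::bind_rows(
    tibble::tibble(subject_id = sprintf("C%d", 1:8), group = "control",
                   measure = "rom_a", value = stats::rnorm(8, 5.5, 1.1)),
    tibble::tibble(subject_id = sprintf("M%d", 1:8), group = "mtss",
                   measure = "rom_a", value = stats::rnorm(8, 9.8, 0.9)),
    tibble::tibble(subject_id = sprintf("C%d", 1:8), group = "control",
                   measure = "rom_b", value = stats::rnorm(8, 3.5, 1.0)),
    tibble::tibble(subject_id = sprintf("M%d", 1:8), group = "mtss",
                   measure = "rom_b", value = stats::rnorm(8, 3.6, 1.0))
  )
  t1 <- build_table1(per)
  expect_named(t1, c("measure", "control_mean", "control_sd", "mtss_mean",
                     "mtss_sd", "es", "p", "sig"))
  expect_equal(t1$sig, t1$p < 0.05)
  expect_true(t1$sig[t1$measure == "rom_a"])
  expect_error(build_table1(per[0, ]), "empty")
})

test_that("tidy and glance methods return one-row summaries", {
  cmp <- unpaired_t_from_summary(5.3, 0.4, 8, 7.8, 1.3, 8, measure = "ev")
  td <- tidy(cmp)
  expect_equal(nrow(td), 1)
  expect_equal(td$effect.size, cmp$es)
  a <- mixed_anova(simulate_binned_angles(offset = 2, seed = 3))
  g <- glance(a)
  expect_equal(nrow(g), 1)
  expect_equal(g$p.interaction, a$p.value[a$term == "group:time"])
})
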