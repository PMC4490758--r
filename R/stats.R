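#' Pooled-variance unpaired t test from group summaries
#'
#' Student's two-sample t test computed from per-group mean, SD and n:
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`,
#' `t0 = (mean2 - mean1) / (sp sqrt(1/n1 + 1/n2))`, two-sided p from the t
#' distribution with `n1+n2-2` df, and the 95 % CI for the mean difference.
#' The pooled (not Welch) form is used throughout: it is the form whose
#' effect size equals Cohen's d with pooled SD (see [effect_size()]).
#'
#' @param mean1,sd1,n1 Control-group summary.
#' @param mean2,sd2,n2 MTSS-group summary.
#' @param measure Optional measure label carried into the result.
#' @param conf_level Confidence level for the interval.
#' @return A `rf_comparison` object (also a one-row list): `measure`,
#'   `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`, `t0`, `df`, `p`,
#'   `ci_lower`, `ci_upper`, `es`.
#' @examples
#' unpaired_t_from_summary(5.5, 1.1, 8, 9.8, 0.9, 8)
#' @export
unpaired_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                    measure = NA_character_,
                                    conf_level = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean2 - mean1
  sed <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  if (sed == 0) {
    if (diff == 0) {
      t0 <- 0; p <- 1
    } else {
      stop("unpaired_t_from_summary: zero pooled variance with nonzero difference",
           call. = FALSE)
    }
  } else {
    t0 <- diff / sed
    p <- 2 * stats::pt(-abs(t0), df)
  }
  tc <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(
    measure = measure, mean1 = mean1, sd1 = sd1, n1 = n1,
    mean2 = mean2, sd2 = sd2, n2 = n2,
    t0 = t0, df = df, p = p,
    ci_lower = diff - tc * sed, ci_upper = diff + tc * sed,
    es = effect_size(t0, n1, n2)
  ), class = "rf_comparison")
}

#' @export
print.rf_comparison <- function(x, ...) {
  cat(sprintf("<rf_comparison>%s t0 = %.3f (df %d), p = %.4g, ES = %.2f\n",
              if (is.na(x$measure)) "" else paste0(" ", x$measure),
              x$t0, x$df, x$p, x$es))
  cat(sprintf("  diff = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean2 - x$mean1, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' @export
tidy.rf_comparison <- function(x, ...) {
  tibble::tibble(measure = x$measure, estimate = x$mean2 - x$mean1,
                 statistic = x$t0, df = x$df, p.value = x$p,
                 conf.low = x$ci_lower, conf.high = x$ci_upper,
                 effect.size = x$es)
}

#' @export
glance.rf_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$t0, df = x$df, p.value = x$p,
                 effect.size = x$es, n1 = x$n1, n2 = x$n2)
}

#' Effect size of the unpaired t test
#'
#' `es = |t0| * sqrt(1/n1 + 1/n2)`, which for the pooled-variance t equals
#' Cohen's d computed with the pooled SD, `|mean2 - mean1| / sp`.
#'
#' @param t0 t statistic (pooled form).
#' @param n1,n2 Group sizes.
#' @return Non-negative effect size.
#' @examples
#' # reference subtalar EV/IV summaries: d = 2.6
#' es <- with(unpaired_t_from_summary(5.3, 0.4, 8, 7.8, 1.3, 8), es)
#' round(es, 1)
#' @export
effect_size <- function(t0, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  abs(t0) * sqrt(1 / n1 + 1 / n2)
}

#' Mixed-design (group x time) ANOVA over stance bins
#'
#' Two-way ANOVA with one between-subject factor (group) and one
#' within-subject factor (time bin), the design used to compare
#' stance-normalized joint angle curves between cohorts. Fitted with
#' [stats::aov()] and an `Error(subject)` stratum: the group effect is
#' tested against subjects-within-group, time and group x time against the
#' within-subject residual. When the interaction is significant at `alpha`,
#' per-bin pooled t tests with Bonferroni correction across bins are
#' attached.
#'
#' @param data Tidy data frame with columns `subject`, `group`, `bin`,
#'   `value` (every subject must have every bin, no missing cells), or an
#'   subjects x bins numeric matrix plus `groups`.
#' @param groups Group label per matrix row (matrix input only).
#' @param alpha Significance level gating the post-hoc comparisons.
#' @return An `rf_anova`: tibble with columns `term`, `df1`, `df2`,
#'   `statistic`, `p.value`, with the post-hoc table (if any) in
#'   `attr(, "posthoc")`.
#' @export
mixed_anova <- function(data, groups = NULL, alpha = 0.05) {
  if (is.matrix(data)) {
    stopifnot(!is.null(groups), length(groups) == nrow(data))
    data <- tibble::tibble(
      subject = rep(sprintf("S%03d", seq_len(nrow(data))), ncol(data)),
      group = rep(as.character(groups), ncol(data)),
      bin = rep(seq_len(ncol(data)), each = nrow(data)),
      value = as.vector(data)
    )
  }
  stopifnot(all(c("subject", "group", "bin", "value") %in% names(data)))
  if (anyNA(data$value)) {
    stop("mixed_anova: missing values are not supported (no imputation)",
         call. = FALSE)
  }
  tab <- table(data$subject, data$bin)
  if (any(tab != 1)) {
    stop("mixed_anova: every subject must contribute exactly one value per bin",
         call. = FALSE)
  }
  if (length(unique(data$group)) != 2) {
    stop("mixed_anova: exactly two groups expected", call. = FALSE)
  }
  d <- data.frame(
    subject = factor(data$subject),
    group = factor(data$group),
    bin = factor(data$bin),
    value = data$value
  )
  if (min(table(unique(d[, c("subject", "group")])$group)) < 2) {
    stop("mixed_anova: need at least 2 subjects per group", call. = FALSE)
  }
  fit <- stats::aov(value ~ group * bin + Error(subject), data = d)
  s <- summary(fit)
  btw <- s[["Error: subject"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  rn <- function(x) trimws(rownames(x))
  out <- tibble::tibble(
    term = c("group", "time", "group:time"),
    df1 = c(btw[rn(btw) == "group", "Df"], wth[rn(wth) == "bin", "Df"],
            wth[rn(wth) == "group:bin", "Df"]),
    df2 = c(btw[rn(btw) == "Residuals", "Df"],
            rep(wth[rn(wth) == "Residuals", "Df"], 2)),
    statistic = c(btw[rn(btw) == "group", "F value"],
                  wth[rn(wth) == "bin", "F value"],
                  wth[rn(wth) == "group:bin", "F value"]),
    p.value = c(btw[rn(btw) == "group", "Pr(>F)"],
                wth[rn(wth) == "bin", "Pr(>F)"],
                wth[rn(wth) == "group:bin", "Pr(>F)"])
  )
  posthoc <- NULL
  if (out$p.value[out$term == "group:time"] < alpha) {
    g <- sort(unique(as.character(d$group)))
    bins <- sort(unique(data$bin))
    posthoc <- dplyr::bind_rows(lapply(bins, function(bb) {
      v1 <- d$value[d$bin == bb & d$group == g[1]]
      v2 <- d$value[d$bin == bb & d$group == g[2]]
      cmp <- unpaired_t_from_summary(mean(v1), stats::sd(v1), length(v1),
                                     mean(v2), stats::sd(v2), length(v2))
      tibble::tibble(bin = bb, statistic = cmp$t0, p.value = cmp$p)
    }))
    posthoc$p.adjusted <- stats::p.adjust(posthoc$p.value, method = "bonferroni")
    posthoc$significant <- posthoc$p.adjusted < alpha
  }
  structure(out, posthoc = posthoc, class = c("rf_anova", class(out)))
}

#' @export
tidy.rf_anova <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rf_anova <- function(x, ...) {
  tibble::tibble(
    f.group = x$statistic[x$term == "group"],
    f.time = x$statistic[x$term == "time"],
    f.interaction = x$statistic[x$term == "group:time"],
    p.interaction = x$p.value[x$term == "group:time"]
  )
}

#' Intraclass correlation for repeated measurements
#'
#' Single-measure ICC from an items x repeats matrix. The default form,
#' ICC(3,1) (two-way mixed, consistency: same fixed rater measuring every
#' item), matches a repeatability design where one investigator repeats the
#' measurement k times; ICC(1,1) (one-way random) and ICC(2,1) (two-way
#' random, absolute agreement) are selectable.
#'
#' @param measurements n x k numeric matrix (n items, k repeats).
#' @param form `"ICC31"`, `"ICC21"` or `"ICC11"`.
#' @return ICC value (scalar). Zero between-item variance gives 0 with a
#'   warning.
#' @export
icc_repeated <- function(measurements, form = c("ICC31", "ICC21", "ICC11")) {
  form <- match.arg(form)
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2, k >= 2, !anyNA(m))
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  msw <- (ss_tot - ss_rows) / (n * (k - 1))
  if (msr <= 1e-15) {
    warning("icc_repeated: zero between-item variance; ICC set to 0")
    return(0)
  }
  switch(form,
    ICC31 = (msr - mse) / (msr + (k - 1) * mse),
    ICC21 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC11 = (msr - msw) / (msr + (k - 1) * msw)
  )
}

#' Normality check (Lilliefors-type Kolmogorov-Smirnov)
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' the sample's mean and SD, with the p-value calibrated by seeded Monte
#' Carlo over normal samples of the same size (the composite-null
#' correction; the naive KS p would be conservative).
#'
#' @param x Numeric sample (n >= 3, non-constant).
#' @param n_mc Monte Carlo replicates.
#' @param seed Integer seed for the Monte Carlo draw.
#' @return List with `statistic` and `p.value`.
#' @export
ks_normality <- function(x, n_mc = 2000, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 3)
  if (stats::sd(x) < 1e-15) {
    stop("ks_normality: constant sample", call. = FALSE)
  }
  lillie_d <- function(v) {
    nn <- length(v)
    z <- sort((v - mean(v)) / stats::sd(v))
    p <- stats::pnorm(z)
    max(max(seq_len(nn) / nn - p), max(p - (seq_len(nn) - 1) / nn))
  }
  d0 <- lillie_d(x)
  dmc <- with_local_seed(seed, {
    vapply(seq_len(n_mc), function(i) lillie_d(stats::rnorm(n)), numeric(1))
  })
  list(statistic = d0, p.value = (1 + sum(dmc >= d0)) / (n_mc + 1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper over [stats::ks.test()] provided alongside the normality
#' check, for comparing the empirical distributions of two groups directly.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  k <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(k$statistic), p.value = k$p.value)
}

#' Group summary table of ROM and static alignment measures
#'
#' Per-measure group means and SDs, pooled t test, effect size and
#' significance marker — the study-style summary table of a cohort result.
#'
#' @param per_subject Tidy tibble with columns `subject_id`, `group`
#'   (`control` / `mtss`), `measure`, `value`; one row per subject and
#'   measure.
#' @param alpha Significance threshold for the star column.
#' @param digits Rounding applied to the reported means/SDs/ES (the
#'   underlying test uses full precision).
#' @return Tibble with columns `measure`, `control_mean`, `control_sd`,
#'   `mtss_mean`, `mtss_sd`, `es`, `p`, `sig`.
#' @export
build_table1 <- function(per_subject, alpha = 0.05, digits = 1) {
  stopifnot(all(c("subject_id", "group", "measure", "value") %in%
                  names(per_subject)))
  if (nrow(per_subject) == 0) {
    stop("build_table1: empty cohort", call. = FALSE)
  }
  measures <- unique(per_subject$measure)
  rows <- lapply(measures, function(ms) {
    d <- per_subject[per_subject$measure == ms, ]
    v1 <- d$value[d$group == "control"]
    v2 <- d$value[d$group == "mtss"]
    if (length(v1) < 2 || length(v2) < 2) {
      stop("build_table1: need >= 2 subjects per group for measure '", ms, "'",
           call. = FALSE)
    }
    cmp <- unpaired_t_from_summary(mean(v1), stats::sd(v1), length(v1),
                                   mean(v2), stats::sd(v2), length(v2),
                                   measure = ms)
    tibble::tibble(
      measure = ms,
      control_mean = round(mean(v1), digits),
      control_sd = round(stats::sd(v1), digits),
      mtss_mean = round(mean(v2), digits),
      mtss_sd = round(stats::sd(v2), digits),
      es = round(cmp$es, digits),
      p = cmp$p,
      sig = cmp$p < alpha
    )
  })
  dplyr::bind_rows(rows)
}
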