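# Group summaries, the two-sample t-test and report rendering.

toy_metrics <- function() {
  tibble::tibble(
    lesion_id = sprintf("L%d", 1:8),
    normalized_area = c(1.0, 3.0, 2.2, 1.8, 0.9, 1.1, 2.5, 2.7),
    net_fluorescence = c(55, 65, 58, 62, 30, 34, 60, 61),
    area_corrected_intensity = c(55, 195, 127.6, 111.6, 27, 37.4, 150, 164.7),
    qc_flags = c("", "", "", "", "", "", "unquantifiable: vessels", "")
  )
}

toy_manifest <- function() {
  tibble::tibble(
    lesion_id = sprintf("L%d", 1:8),
    animal_id = rep(c("R1", "R2", "R3", "R4"), each = 2),
    eye = "OS",
    group = rep(c("PBS", "anti-VEGF"), each = 4),
    week = c(2, 2, 2, 2, 2, 2, 2, 1)
  )
}

test_that("summaries give mean and SD per group/week and log exclusions", {
  s <- summarize_lesions(toy_metrics(), toy_manifest())
  pbs_area <- dplyr::filter(s, group == "PBS", metric == "normalized_area")
  expect_equal(pbs_area$n, 4)
  expect_equal(pbs_area$mean, mean(c(1.0, 3.0, 2.2, 1.8)))
  expect_equal(pbs_area$sd, sd(c(1.0, 3.0, 2.2, 1.8)))

  ex <- attr(s, "excluded")
  expect_equal(ex$qc_flagged, 1)       # L7
  expect_equal(ex$week_excluded, 1)    # L8 (week 1)
  expect_equal(ex$included + ex$qc_flagged + ex$week_excluded, 8)

  av_area <- dplyr::filter(s, group == "anti-VEGF", metric == "normalized_area")
  expect_equal(av_area$n, 2)           # L5, L6 only

  # two lesions {1, 3}: mean 2, sd sqrt(2)
  two <- summarize_lesions(
    tibble::tibble(lesion_id = c("a", "b"), normalized_area = c(1, 3),
                   group = "G", week = 2))
  expect_equal(two$mean, 2); expect_equal(two$sd, sqrt(2))
})

test_that("summaries are invariant to input row order", {
  m <- toy_metrics(); mf <- toy_manifest()
  s1 <- summarize_lesions(m, mf)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  s2 <- summarize_lesions(m[perm, ], mf)
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("orphan lesions are a manifest error; single-lesion groups skip tests", {
  m <- toy_metrics()
  expect_error(summarize_lesions(m, toy_manifest()[-3, ]),
               regexp = "L3", class = "ffa_data_error")

  one <- tibble::tibble(lesion_id = c("a", "b", "c"),
                        normalized_area = c(1, 2, 5),
                        group = c("G1", "G1", "G2"), week = 2)
  s <- summarize_lesions(one)
  expect_equal(dplyr::filter(s, group == "G2")$n, 1)
  expect_equal(nrow(compare_groups(one)), 0)  # n < 2 on one side
})

test_that("pooled t-test matches the closed-form computation to 1e-10", {
  a <- c(1.1, 2.4, 3.0); b <- c(2.0, 4.5, 6.1)
  tt <- ttest_two_tailed(a, b)
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(tt$t, t_ref, tolerance = 1e-10)
  expect_equal(tt$p_value, p_ref, tolerance = 1e-10)
  expect_equal(tt$df, 4)
})

test_that("identical samples give t = 0, p = 1; separated samples p < 0.001", {
  a <- c(1, 2, 3)
  expect_equal(ttest_two_tailed(a, a)$p_value, 1)
  expect_equal(ttest_two_tailed(a, a)$t, 0)
  tt <- ttest_two_tailed(a, a + 10)
  expect_lt(tt$p_value, 0.001)
  # zero variance in both with equal means: the p = 1 convention
  expect_equal(ttest_two_tailed(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(ttest_two_tailed(1, c(1, 2)), class = "ffa_data_error")
})

test_that("welch variant differs from pooled under unequal variances", {
  set.seed(3)
  a <- rnorm(10, 0, 1); b <- rnorm(25, 1, 6)
  tp <- ttest_two_tailed(a, b, "pooled")
  tw <- ttest_two_tailed(a, b, "welch")
  expect_false(isTRUE(all.equal(tp$df, tw$df)))
})

test_that("compare_groups tests every week/metric pair without correction", {
  m <- toy_metrics()[1:6, ]; mf <- toy_manifest()[1:6, ]
  tests <- compare_groups(m, mf)
  expect_true(all(c("normalized_area", "net_fluorescence",
                    "area_corrected_intensity") %in% tests$metric))
  nf <- dplyr::filter(tests, metric == "net_fluorescence")
  expect_setequal(c(nf$group_a, nf$group_b), c("PBS", "anti-VEGF"))
  # net fluorescence separates cleanly in the toy data
  expect_lt(nf$p_value, 0.01)

  holm <- compare_groups(m, mf, p_adjust = "holm")
  expect_true(all(holm$p_value >= tests$p_value))
})

test_that("phantom-style cohort recovers programmed group means within SE", {
  set.seed(14)
  n <- 16
  dat <- tibble::tibble(
    lesion_id = sprintf("L%d", 1:(2 * n)),
    normalized_area = c(rnorm(n, 2.0, 0.3), rnorm(n, 1.4, 0.3)),
    group = rep(c("PBS", "anti-VEGF"), each = n), week = 2)
  s <- summarize_lesions(dat)
  # summaries reproduce the direct group statistics exactly ...
  ref_mean <- tapply(dat$normalized_area, dat$group, mean)
  ref_sd <- tapply(dat$normalized_area, dat$group, sd)
  for (g in c("PBS", "anti-VEGF")) {
    row <- dplyr::filter(s, group == g)
    expect_equal(row$mean, unname(ref_mean[g]))
    expect_equal(row$sd, unname(ref_sd[g]))
    # ... and sit within 3 standard errors of the programmed population mean
    truth <- if (g == "PBS") 2.0 else 1.4
    expect_lt(abs(row$mean - truth), 3 * row$sd / sqrt(row$n))
  }
})

test_that("report bundle writes tables and one figure per metric", {
  m <- toy_metrics()[1:6, ]; mf <- toy_manifest()[1:6, ]
  s <- summarize_lesions(m, mf)
  tt <- compare_groups(m, mf)
  out <- withr::local_tempdir()
  paths <- render_report(s, tt, out)
  expect_true(file.exists(file.path(out, "summaries.csv")))
  expect_true(file.exists(file.path(out, "tests.csv")))
  expect_true(file.exists(file.path(out, "normalized_area.png")))
  # empty tests: tables only, no tests.csv, charts still render
  out2 <- withr::local_tempdir()
  render_report(s, NULL, out2)
  expect_false(file.exists(file.path(out2, "tests.csv")))
  expect_true(file.exists(file.path(out2, "net_fluorescence.png")))
})

test_that("significance stars follow the figure-legend thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})
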