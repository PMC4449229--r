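# Traces, appearance/peak detection, model fits and analysis-frame choice.

test_that("constant frames give a flat trace; 1-frame traces are degenerate", {
  frames <- replicate(5, matrix(12, 20, 20), simplify = FALSE)
  seq1 <- frame_sequence(frames, 0:4)
  msk <- matrix(FALSE, 20, 20); msk[5:15, 5:15] <- TRUE
  tr <- extract_trace(seq1, msk, lesion_id = "flat")
  expect_equal(tr$mean_grey, rep(12, 5))
  expect_equal(tr$time, 0:4)

  one <- frame_sequence(frames[1], 0)
  tr1 <- extract_trace(one, msk)
  expect_equal(nrow(tr1), 1)
  expect_error(detect_appearance(tr1), class = "ffa_data_error")
})

test_that("phantom lesion trace equals the programmed curve plus background", {
  times <- seq(0, 20, by = 0.5)
  sc <- small_scene(delta = 60, noise = 0, mottle = 0, halo = 0, times = times)
  g <- extract_green(sc$sequence)
  tr <- extract_trace(g, sc$truth$lesion_masks[[1]], sc$truth$vessel_mask)
  k <- sc$truth$kinetics$lesion
  prog <- 60 * gamma_variate(times, 1, k$t0, k$theta, k$alpha)
  # subtract the simultaneously-rendered background trace
  bgpix <- !sc$truth$lesion_masks[[1]] & !sc$truth$vessel_mask &
    !sc$truth$onh_mask
  bgtr <- extract_trace(g, bgpix)
  expect_lt(max(abs((tr$mean_grey - bgtr$mean_grey) - prog)), 1)  # rounding only
})

test_that("appearance detection finds step onsets and honours persistence", {
  tr <- ffaquant:::new_trace(0:14, c(rep(0, 10), rep(100, 5)))
  app <- detect_appearance(tr)
  expect_true(app$defined)
  expect_equal(app$appearance_time, 10)

  # single-frame spike is not an appearance
  spike <- ffaquant:::new_trace(0:14, c(rep(0, 7), 50, rep(0, 7)))
  expect_false(detect_appearance(spike)$defined)

  # flat noisy trace: no crossing at k = 3
  set.seed(2)
  flat <- ffaquant:::new_trace(0:99, rnorm(100, 10, 1))
  expect_false(detect_appearance(flat)$defined)
})

test_that("programmed IV appearance is detected within two frame intervals", {
  tr <- simulate_trace(iv_schedule_times(), "IV", A = 120, t0 = 7.45,
                       theta = 2.77, alpha = 2, baseline = 12,
                       noise_sd = 1, seed = 4)
  app <- detect_appearance(tr)
  expect_true(app$defined)
  # detection threshold sits slightly up the rising limb; allow the
  # documented two frame intervals plus the rise to 3 SD above baseline
  expect_gte(app$appearance_time, 7.45 - 2 / 30)
  expect_lt(app$appearance_time, 8.2)
})

test_that("peak detection matches the analytic gamma-variate maximum", {
  tr <- simulate_trace(iv_schedule_times(), "IV", A = 120, t0 = 7.0,
                       theta = 3.2, alpha = 2, baseline = 12, noise_sd = 0)
  pk <- detect_peak(tr)
  expect_false(pk$censored)
  expect_lt(abs(pk$peak_time - 10.2), 1 / 30 + 1e-9)

  # noiseless unimodal trace: exact argmax frame
  sub <- ffaquant:::new_trace(tr$time, tr$mean_grey)
  pk1 <- detect_peak(sub, smooth_window = 1)
  expect_equal(pk1$peak_time, tr$time[which.max(tr$mean_grey)])
})

test_that("monotone and IP-schedule traces are censored at the window end", {
  mono <- ffaquant:::new_trace(0:50, seq(0, 100, length.out = 51))
  expect_true(detect_peak(mono)$censored)

  # structural IP property: a log-rise over the 10-minute window never
  # attains an interior maximum, so its peak is right-censored
  tr <- simulate_trace(ip_schedule_times(), "IP", A = 30, t0 = 22.5, tau = 40,
                       baseline = 10, noise_sd = 0, seed = 9)
  pk <- detect_peak(tr)
  expect_true(pk$censored)
  expect_equal(pk$peak_time, 595)
})

test_that("appearance never exceeds the peak when both are defined", {
  for (s in 1:20) {
    tr <- simulate_trace(seq(0, 120, by = 1 / 30), "IV",
                         A = runif(1, 60, 150), t0 = runif(1, 5, 9),
                         theta = runif(1, 2, 5), alpha = runif(1, 1.2, 3),
                         baseline = 12, noise_sd = 2, seed = s)
    app <- detect_appearance(tr)
    pk <- detect_peak(tr)
    if (app$defined && !pk$censored) {
      expect_lte(app$appearance_time, pk$peak_time)
    }
  }
})

test_that("IV gamma-variate fits recover theta and the peak time", {
  tr <- simulate_trace(iv_schedule_times(), "IV", A = 120, t0 = 7.0,
                       theta = 3.2, alpha = 2, baseline = 12,
                       noise_sd = 2, seed = 21)
  fit <- fit_kinetics(tr, "IV")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$theta - 3.2) / 3.2, 0.05)
  expect_lt(abs(fit$peak_time - 10.2), 0.2)
  td <- tidy(fit)
  expect_setequal(td$term, c("b0", "A", "t0", "theta", "alpha"))
  expect_true(glance(fit)$converged)
})

test_that("IP log-rise fits recover the appearance delay", {
  tr <- simulate_trace(ip_schedule_times(), "IP", A = 30, t0 = 22.5, tau = 40,
                       baseline = 10, noise_sd = 1, seed = 33)
  fit <- fit_kinetics(tr, "IP")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$t0 - 22.5) / 22.5, 0.10)
})

test_that("flat traces yield a fit-failed flag, not an error", {
  set.seed(5)
  tr <- ffaquant:::new_trace(0:99, rnorm(100, 20, 0.5))
  fit <- fit_kinetics(tr, "IV")
  expect_false(fit$converged)
  expect_match(fit$reason, "appearance")
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("analysis frame selection is nearest-in-time with clamping", {
  s30 <- frame_sequence(replicate(400, matrix(0, 2, 2), simplify = FALSE),
                        (0:399) / 30)
  expect_equal(select_analysis_frame(s30, 10.2), 307)  # t = 10.200 s
  s1 <- frame_sequence(replicate(30, matrix(0, 2, 2), simplify = FALSE), 0:29)
  expect_equal(select_analysis_frame(s1, 10.2), 11)    # t = 10 s nearest
  expect_warning(idx <- select_analysis_frame(s1, 99), class = "ffa_out_of_range")
  expect_equal(idx, 30)
})
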