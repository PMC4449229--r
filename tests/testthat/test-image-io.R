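# Sequence container, acquisition schedules, TIFF and ROI file round-trips.

test_that("constant-rate and piecewise schedules produce the stated timestamps", {
  expect_equal(schedule_times(1, 120), 0:119)
  t_ip <- ip_schedule_times()
  # independent enumeration of the piecewise schedule
  expect_equal(t_ip, c(seq(0, 119, by = 1), seq(120, 595, by = 5)))
  expect_length(t_ip, 216)
  expect_equal(max(t_ip), 595)
  expect_length(iv_schedule_times(), 3600)
})

test_that("frame_sequence validates dimensions, range and monotone times", {
  f <- matrix(0L, 4, 5)
  expect_s3_class(frame_sequence(list(f, f), c(0, 1)), "frame_sequence")
  expect_error(frame_sequence(list(f, matrix(0L, 5, 4)), c(0, 1)),
               class = "ffa_format_error")
  expect_error(frame_sequence(list(f, f), c(1, 1)), class = "ffa_schedule_error")
  expect_error(frame_sequence(list(f, f), c(1, 0)), class = "ffa_schedule_error")
  expect_error(frame_sequence(list(matrix(300, 2, 2)), 0, bit_depth = 8),
               class = "ffa_format_error")
})

test_that("TIFF write/read round-trips grey values bit-exactly", {
  set.seed(7)
  frames <- replicate(3, matrix(sample(0:255, 24 * 32, TRUE), 24, 32),
                      simplify = FALSE)
  seq0 <- frame_sequence(frames, c(0, 0.5, 1.2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_sequence(seq0, path)
  seq1 <- read_frame_sequence(path, times = c(0, 0.5, 1.2))
  expect_identical(lapply(seq1$frames, as.integer),
                   lapply(seq0$frames, as.integer))
  expect_equal(seq1$bit_depth, 8)
})

test_that("RGB sequences round-trip and timestamps come from the schedule", {
  set.seed(8)
  fr <- array(sample(0:255, 16 * 20 * 3, TRUE), dim = c(16, 20, 3))
  seq0 <- frame_sequence(list(fr, fr, fr), c(0, 1, 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_sequence(seq0, path)
  seq1 <- read_frame_sequence(path, rates = 1)
  expect_equal(seq1$times, c(0, 1, 2))
  expect_equal(n_channels(seq1), 3)
  expect_identical(as.integer(seq1$frames[[2]]), as.integer(fr))
})

test_that("green-channel extraction picks channel 2 and leaves values untouched", {
  fr <- array(0, dim = c(10, 12, 3))
  fr[, , 1] <- 10; fr[, , 3] <- 30
  fr[, , 2] <- matrix(rep(0:11, each = 10), 10, 12)  # x-coordinate ramp
  seq0 <- frame_sequence(list(fr), 0)
  g <- extract_green(seq0)
  expect_equal(n_channels(g), 1)
  expect_identical(g$frames[[1]], fr[, , 2])

  # pixel-level selection
  fr2 <- array(c(10, 200, 30), dim = c(1, 1, 3))
  g2 <- extract_green(frame_sequence(list(fr2), 0))
  expect_equal(as.vector(g2$frames[[1]]), 200)

  # idempotent via the no-op branch
  expect_warning(g3 <- extract_green(g), class = "ffa_already_grey")
  expect_identical(g3$frames, g$frames)
})

test_that("polygon JSON ROI sidecars round-trip", {
  rois <- roi_set(list(
    lesion_roi("L1", "CNV", vertices = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))),
    lesion_roi("ONH", "ONH", vertices = disc_polygon(30, 30, 8, n = 12))))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_set(rois, path, "json")
  back <- read_roi_set(path, "json")
  expect_equal(length(back), 2)
  expect_equal(back$rois[[1]]$vertices, rois$rois[[1]]$vertices,
               ignore_attr = TRUE)
  expect_equal(back$rois[[2]]$role, "ONH")
})

test_that("ImageJ .roi files round-trip integer freehand outlines", {
  v <- cbind(c(3, 25, 30, 14, 2), c(4, 2, 20, 28, 15))
  dir <- withr::local_tempdir()
  rois <- roi_set(list(lesion_roi("L1", "CNV", vertices = v)))
  write_roi_set(rois, dir, "imagej")
  back <- read_roi_set(dir, "imagej")
  expect_equal(back$rois[[1]]$vertices, v, ignore_attr = TRUE)
  expect_equal(back$rois[[1]]$lesion_id, "L1")
  expect_equal(back$rois[[1]]$role, "CNV")

  # freehand subtype byte is also accepted
  f2 <- file.path(dir, "L2__CNV.roi")
  write_imagej_roi(v, f2, type = 7L)
  expect_equal(read_imagej_roi(f2), v, ignore_attr = TRUE)
})

test_that("roi dialect pairs preserve rasterized pixel membership", {
  shape <- c(64, 64)
  v <- disc_polygon(30, 32, 14, n = 40)
  rois <- roi_set(list(lesion_roi("L1", "CNV", vertices = round(v))))
  ref <- rasterize_roi(rois$rois[[1]], shape)

  d_json <- withr::local_tempfile(fileext = ".json")
  d_ij <- withr::local_tempdir()
  d_mask <- withr::local_tempdir()
  write_roi_set(rois, d_json, "json")
  write_roi_set(rois, d_ij, "imagej")
  write_roi_set(rois, d_mask, "mask", frame_shape = shape)
  for (got in list(read_roi_set(d_json, "json"),
                   read_roi_set(d_ij, "imagej"),
                   read_roi_set(d_mask, "mask"))) {
    expect_identical(rasterize_roi(got$rois[[1]], shape), ref)
  }
})

test_that("mask dialect: filled disc mask area equals the mask pixel count", {
  shape <- c(64, 64)
  disc <- lesion_roi("d", "CNV", vertices = disc_polygon(32, 32, 20, n = 80))
  m <- rasterize_roi(disc, shape)
  dir <- withr::local_tempdir()
  write_roi_set(roi_set(list(lesion_roi("d", "CNV", mask = m))), dir, "mask",
                frame_shape = shape)
  back <- read_roi_set(dir, "mask")
  expect_equal(roi_area_px(back$rois[[1]], shape), sum(m))
})

test_that("degenerate and malformed ROI inputs are rejected with context", {
  expect_error(lesion_roi("bad", "CNV", vertices = cbind(1:2, 1:2)),
               regexp = "bad", class = "ffa_data_error")
  expect_error(read_roi_set(withr::local_tempfile(), "json"),
               class = "ffa_format_error")
  dir <- withr::local_tempdir()
  writeBin(as.raw(1:80), file.path(dir, "x__CNV.roi"))
  expect_error(read_roi_set(dir, "imagej"), class = "ffa_format_error")
})
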