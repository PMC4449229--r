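# Lesion means, background patch sampling, net fluorescence, the
# area-corrected score and flatmount conversion.

test_that("lesion mean grey averages lesion pixels outside the vessel mask", {
  fr <- matrix(77, 30, 30)
  msk <- matrix(FALSE, 30, 30); msk[10:20, 10:20] <- TRUE
  expect_equal(lesion_mean_grey(fr, msk), 77)

  # 10 pixels valued 0..9, vessels cover the two largest
  fr2 <- matrix(0, 5, 5); msk2 <- matrix(FALSE, 5, 5); ves <- matrix(FALSE, 5, 5)
  fr2[1, 1:5] <- 0:4; fr2[2, 1:5] <- 5:9
  msk2[1:2, 1:5] <- TRUE
  ves[2, 4:5] <- TRUE
  expect_equal(lesion_mean_grey(fr2, msk2, ves), mean(0:7))

  # random frame + random masks vs per-pixel summation oracle
  set.seed(11)
  fr3 <- matrix(runif(400, 0, 255), 20, 20)
  m3 <- matrix(runif(400) < 0.3, 20, 20)
  v3 <- matrix(runif(400) < 0.2, 20, 20)
  if (!any(m3 & !v3)) m3[1, 1] <- TRUE
  acc <- 0; n <- 0
  for (i in 1:20) for (j in 1:20) {
    if (m3[i, j] && !v3[i, j]) { acc <- acc + fr3[i, j]; n <- n + 1 }
  }
  expect_equal(lesion_mean_grey(fr3, m3, v3), acc / n)

  expect_error(lesion_mean_grey(fr2, msk2, msk2, lesion_id = "X"),
               regexp = "X", class = "ffa_unquantifiable_error")
})

make_annulus <- function(r = 25, ctr = c(100, 100), shape = c(200, 200)) {
  build_annulus(lesion_roi("L", "CNV", vertices = disc_polygon(ctr[1], ctr[2], r)),
                shape)
}

test_that("uniform background gives its exact grey for any seed", {
  fr <- matrix(40, 200, 200)
  ann <- make_annulus()
  for (s in c(1, 7, 123)) {
    bg <- sample_background(fr, ann, patch_side = 5, seed = s)
    expect_equal(bg$background_mean, 40)
    expect_equal(length(bg$patch_means), 6)
  }
})

test_that("background patches avoid vessels by construction", {
  fr <- matrix(40, 200, 200)
  ves <- matrix(FALSE, 200, 200)
  ves[, seq(10, 190, by = 24)] <- TRUE           # bright vessel columns
  fr[ves] <- 200
  ann <- make_annulus()
  bg <- sample_background(fr, ann, vessel_mask = ves, patch_side = 5, seed = 3)
  expect_equal(bg$background_mean, 40)
})

test_that("patch selection is deterministic and reproducible step by step", {
  set.seed(99)
  fr <- matrix(40 + rnorm(200 * 200, 0, 5), 200, 200)
  ann <- make_annulus()
  bg1 <- sample_background(fr, ann, patch_side = 5, seed = 11)
  bg2 <- sample_background(fr, ann, patch_side = 5, seed = 11)
  expect_identical(bg1$patch_centers, bg2$patch_centers)
  expect_identical(bg1$background_mean, bg2$background_mean)

  # reference re-implementation of the documented selection rule:
  # candidates = centres whose full patch fits in the annulus (column-major
  # order), ranked by angular distance to 6 targets 60 degrees apart with a
  # seeded start angle and seeded tie-breaks, patches disjoint (Chebyshev
  # distance >= side)
  s <- 5L; lo <- -2L; hi <- 2L
  allowed <- ann$mask
  h <- nrow(allowed); w <- ncol(allowed)
  fits <- matrix(FALSE, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!allowed[i, j]) next
    ri <- (i + lo):(i + hi); cj <- (j + lo):(j + hi)
    if (min(ri) < 1 || max(ri) > h || min(cj) < 1 || max(cj) > w) next
    fits[i, j] <- all(allowed[ri, cj])
  }
  cand <- which(fits, arr.ind = TRUE)
  cx <- cand[, 2] - 1; cy <- cand[, 1] - 1
  ang <- (atan2(cy - ann$centroid["y"], cx - ann$centroid["x"]) * 180 / pi) %% 360
  set.seed(11L)
  start <- runif(1, 0, 60); tie <- runif(length(ang))
  picked <- integer(0)
  for (tgt in (start + (0:5) * 60) %% 360) {
    d <- abs((ang - tgt) %% 360); d <- pmin(d, 360 - d)
    for (i in order(d, tie)) {
      if (length(picked) == 0 ||
          all(pmax(abs(cx[i] - cx[picked]), abs(cy[i] - cy[picked])) >= s)) {
        picked <- c(picked, i); break
      }
    }
  }
  expect_equal(bg1$patch_centers$x, cx[picked])
  expect_equal(bg1$patch_centers$y, cy[picked])
})

test_that("insufficient vessel-free annulus raises an unquantifiable error", {
  fr <- matrix(40, 120, 120)
  ann <- make_annulus(r = 15, ctr = c(60, 60), shape = c(120, 120))
  ves <- matrix(TRUE, 120, 120)  # everything is vessel
  expect_error(
    sample_background(fr, ann, vessel_mask = ves, patch_side = 5,
                      seed = 1, lesion_id = "L9"),
    regexp = "L9", class = "ffa_unquantifiable_error")
})

test_that("net fluorescence subtracts background and admits negatives", {
  expect_equal(net_fluorescence(100, 40), 60)
  expect_equal(net_fluorescence(40, 40), 0)
  expect_equal(net_fluorescence(25, 40), -15)
})

test_that("area-corrected intensity is the bilinear product", {
  expect_equal(area_corrected_intensity(60, 2.5), 150)
  expect_equal(area_corrected_intensity(0, 7.3), 0)
  expect_equal(area_corrected_intensity(-15, 1.2), -18)
  # bilinearity
  expect_equal(area_corrected_intensity(2 * 37, 1.4),
               2 * area_corrected_intensity(37, 1.4))
  expect_equal(area_corrected_intensity(37, 2 * 1.4),
               2 * area_corrected_intensity(37, 1.4))
})

test_that("flatmount pixel areas convert through the squared scale", {
  expect_equal(flatmount_area_um2(10000, 100, 500), 250000)
  expect_equal(flatmount_area_um2(1, 1, 1), 1)
  # rasterized disc r = 100 px at 2 um/px is close to pi * 200^2 um2
  d <- lesion_roi("d", "CNV", vertices = disc_polygon(110, 110, 100))
  a <- roi_area_px(d, c(221, 221))
  expect_lt(abs(flatmount_area_um2(a, 1, 2) - pi * 200^2) / (pi * 200^2), 0.01)
  expect_error(flatmount_area_um2(10, 0, 500), class = "ffa_data_error")
})

test_that("noiseless phantom recovers the painted contrast exactly", {
  sc <- small_scene(delta = 60, noise = 0, mottle = 0, halo = 0)
  m <- quantify_scene(sc$sequence, sc$rois, seed = 5)
  expect_equal(m$net_fluorescence, 60)
  expect_equal(m$area_corrected_intensity, 60 * m$normalized_area)

  burn <- small_scene(delta = -15, role = "CR_burn", noise = 0, mottle = 0)
  mb <- quantify_scene(burn$sequence, burn$rois, seed = 5)
  expect_equal(mb$net_fluorescence, -15)
  expect_lt(mb$area_corrected_intensity, 0)
})

test_that("with additive noise the net error shrinks with pixel count", {
  errs <- vapply(1:10, function(s) {
    sc <- small_scene(delta = 60, noise = 4, mottle = 0, halo = 0, seed = s)
    m <- quantify_scene(sc$sequence, sc$rois, seed = 1)
    m$net_fluorescence - 60
  }, 0)
  # lesion has ~2700 px; SE of the lesion mean ~ 4/sqrt(2700) << 1;
  # the background mean over 6 small patches dominates but stays < 1 grey
  expect_lt(median(abs(errs)), 1)
})
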