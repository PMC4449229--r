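# Synthetic fundus phantom generator.
#
# Emulates the appearance of rodent fluorescein fundus angiograms well
# enough to exercise every stage of the quantification pipeline with known
# ground truth: a mottled choroidal background, a seeded branching vessel
# tree, the optic nerve head disc, hyperfluorescent CNV lesions with an
# optional diffuse leak halo, hypofluorescent chorio-retinal burns, per-
# compartment bolus kinetics for intravenous and intraperitoneal
# administration, a per-session magnification factor, and additive Gaussian
# noise. The signal lives in the green channel of the rendered 24-bit RGB
# frames; red and blue carry low-amplitude decoy content so that channel
# extraction is itself under test. Everything is regenerable bit-exactly
# from (spec, seed).

# Per-compartment bolus timing (seconds). Intravenous values reproduce the
# observed appearance/peak ordering: vessels fill first, then optic nerve
# and choroid, the lesion last, with all peaks near 10.1-10.2 s.
IV_KINETICS <- list(
  vessel  = list(t0 = 6.55, theta = 3.56, alpha = 2),
  onh     = list(t0 = 7.18, theta = 2.93, alpha = 2),
  choroid = list(t0 = 7.27, theta = 2.84, alpha = 2),
  lesion  = list(t0 = 7.45, theta = 2.77, alpha = 2)
)
IP_KINETICS <- list(
  vessel  = list(t0 = 22.50, tau = 60),
  onh     = list(t0 = 22.58, tau = 60),
  choroid = list(t0 = 32.83, tau = 60),
  lesion  = list(t0 = 33.33, tau = 60)
)

# normalized kinetic weight in [0, 1] for a compartment at times t
kinetic_weight <- function(t, route, comp, window_end = 600) {
  if (route == "IV") {
    p <- IV_KINETICS[[comp]]
    gamma_variate(t, A = 1, t0 = p$t0, theta = p$theta, alpha = p$alpha)
  } else {
    p <- IP_KINETICS[[comp]]
    log_rise(t, A = 1, t0 = p$t0, tau = p$tau) /
      log1p((window_end - p$t0) / p$tau)
  }
}

regular_ellipse_polygon <- function(cx, cy, rx, ry, n = 48) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + rx * cos(a), y = cy + ry * sin(a))
}

#' Specify a synthetic fundus scene
#'
#' Defaults describe a typical session: XGA frames (1024 x 768, 8 bits per
#' channel), a mottled choroidal background around grey 40, an optic nerve
#' head disc of radius 48 px, a seeded vessel tree, and four laser spots
#' placed radially 2-3 disc diameters from the optic nerve head -- three
#' hyperfluorescent CNV lesions (peak contrast +60 grey) and one
#' hypofluorescent chorio-retinal burn (-15 grey).
#'
#' @param width,height Frame dimensions in pixels.
#' @param bit_depth Bits per channel.
#' @param background_grey Choroidal background level at its bolus peak.
#' @param base_floor Constant camera offset present before dye arrival.
#' @param mottle_amplitude SD of the smooth background mottle (grey levels).
#' @param mottle_scale Mottle correlation length (pixels).
#' @param onh_center,onh_radius Optic nerve head disc geometry (pixels).
#' @param n_vessels Number of main vessel branches leaving the disc.
#' @param vessel_grey Vessel contrast at bolus peak (grey levels).
#' @param lesions Tibble with columns `lesion_id`, `role` (CNV/CR_burn),
#'   `cx`, `cy`, `rx`, `ry`, `delta_grey`, `halo_width`; `NULL` for the
#'   default four-spot layout.
#' @param route `"IV"` or `"IP"` administration.
#' @param times Frame timestamps (seconds); `NULL` renders the single
#'   cohort analysis frame (10.2 s for IV, end of window for IP).
#' @param magnification Per-session magnification factor (0.8-1.25).
#' @param noise_sd Additive Gaussian noise SD (grey levels).
#' @param seed Integer seed; the scene is a pure function of (spec, seed).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1024, height = 768, bit_depth = 8,
                       background_grey = 40, base_floor = 10,
                       mottle_amplitude = 4, mottle_scale = 32,
                       onh_center = c(width * 0.42, height * 0.5),
                       onh_radius = 48,
                       n_vessels = 6, vessel_grey = 70,
                       lesions = NULL,
                       route = c("IV", "IP"), times = NULL,
                       magnification = 1, noise_sd = 2, seed = 1L) {
  route <- match.arg(route)
  if (magnification < 0.8 || magnification > 1.25) {
    stop_data("magnification must lie in [0.8, 1.25]")
  }
  if (is.null(lesions)) {
    dd <- 2 * onh_radius
    ang <- c(-60, 10, 70, 150) * pi / 180
    dist <- c(2.3, 2.6, 2.4, 2.5) * dd
    lesions <- tibble(
      lesion_id = c("L1", "L2", "L3", "B1"),
      role = c("CNV", "CNV", "CNV", "CR_burn"),
      cx = onh_center[1] + dist * cos(ang),
      cy = onh_center[2] + dist * sin(ang),
      rx = c(62, 55, 68, 45), ry = c(58, 60, 62, 45),
      delta_grey = c(60, 60, 60, -15),
      halo_width = c(8, 8, 8, 0)
    )
  }
  lesions <- as_tibble(lesions)
  need <- c("lesion_id", "role", "cx", "cy", "rx", "ry", "delta_grey", "halo_width")
  missing_cols <- setdiff(need, names(lesions))
  if (length(missing_cols)) {
    stop_data(sprintf("lesion table lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  bad <- (lesions$role == "CNV" & lesions$delta_grey <= 0) |
    (lesions$role == "CR_burn" & lesions$delta_grey >= 0)
  if (any(bad)) {
    stop_data("CNV lesions must have positive delta_grey, CR burns negative")
  }
  if (is.null(times)) times <- if (route == "IV") 10.2 else 595
  structure(
    list(width = as.integer(width), height = as.integer(height),
         bit_depth = as.integer(bit_depth),
         background_grey = background_grey, base_floor = base_floor,
         mottle_amplitude = mottle_amplitude, mottle_scale = mottle_scale,
         onh_center = as.double(onh_center), onh_radius = onh_radius,
         n_vessels = as.integer(n_vessels), vessel_grey = vessel_grey,
         lesions = lesions, route = route, times = as.double(times),
         magnification = magnification, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# smooth mottle field: seeded coarse Gaussian grid, bilinear upsampling
render_mottle <- function(height, width, scale, amplitude) {
  if (amplitude <= 0) return(matrix(0, height, width))
  gh <- ceiling(height / scale) + 2L
  gw <- ceiling(width / scale) + 2L
  grid <- matrix(rnorm(gh * gw), gh, gw)
  y <- (seq_len(height) - 1) / scale + 1
  x <- (seq_len(width) - 1) / scale + 1
  yi <- pmin(floor(y), gh - 1L); xf <- x - floor(x); yf <- y - floor(y)
  xi <- pmin(floor(x), gw - 1L)
  g00 <- grid[yi, xi]; g10 <- grid[yi + 1L, xi]
  g01 <- grid[yi, xi + 1L]; g11 <- grid[yi + 1L, xi + 1L]
  wy <- matrix(yf, height, width); wx <- matrix(xf, height, width, byrow = TRUE)
  amplitude * ((1 - wy) * (1 - wx) * g00 + wy * (1 - wx) * g10 +
                 (1 - wy) * wx * g01 + wy * wx * g11)
}

# seeded branching random-walk vessel tree; returns a logical mask
render_vessel_tree <- function(height, width, center, n_main, start_radius,
                               magnification = 1) {
  mask <- matrix(FALSE, height, width)
  stamp <- function(cx, cy, r) {
    r <- max(r, 1)
    x1 <- max(0, floor(cx - r)); x2 <- min(width - 1, ceiling(cx + r))
    y1 <- max(0, floor(cy - r)); y2 <- min(height - 1, ceiling(cy + r))
    if (x1 > x2 || y1 > y2) return()
    xr <- x1:x2; yr <- y1:y2
    dx <- matrix(xr - cx, length(yr), length(xr), byrow = TRUE)
    dy <- matrix(yr - cy, length(yr), length(xr))
    hit <- dx^2 + dy^2 <= r^2
    mask[yr + 1L, xr + 1L][hit] <<- TRUE
  }
  walk <- function(x, y, dir, width_px, depth) {
    step <- 4 * magnification
    n_steps <- round(runif(1, 40, 90))
    for (i in seq_len(n_steps)) {
      x <- x + step * cos(dir); y <- y + step * sin(dir)
      if (x < -20 || x > width + 20 || y < -20 || y > height + 20) break
      stamp(x, y, width_px / 2)
      dir <- dir + rnorm(1, 0, 0.12)
      width_px <- max(width_px * 0.995, 2.5 * magnification)
      if (depth < 2 && runif(1) < 0.02) {
        walk(x, y, dir + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
             width_px * 0.8, depth + 1)
      }
    }
  }
  angles <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n_main) - 1) / n_main +
    rnorm(n_main, 0, 0.15)
  for (a in angles) {
    walk(center[1] + start_radius * cos(a) * 0.6,
         center[2] + start_radius * sin(a) * 0.6,
         a, runif(1, 5, 8) * magnification, 0)
  }
  mask
}

#' Render a synthetic fundus scene
#'
#' Produces the RGB frame sequence, the ROI set a grader would have drawn
#' (lesion, ONH and vessel outlines/masks), and the full ground truth. The
#' scene is deterministic given the spec (which includes the seed); the
#' caller's RNG state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return List with elements `sequence` ([frame_sequence()], RGB), `rois`
#'   ([roi_set()]), `truth` (list: per-role masks, per-lesion areas and
#'   contrasts, normalized areas, kinetics parameters, timestamps,
#'   magnification).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  seed_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  h <- spec$height; w <- spec$width; m <- spec$magnification
  ctr <- c(w / 2, h / 2)  # magnification acts about the optical axis
  mag <- function(p) ctr + m * (p - ctr)

  onh_c <- mag(spec$onh_center)
  onh_r <- spec$onh_radius * m
  onh_poly <- regular_ellipse_polygon(onh_c[1], onh_c[2], onh_r, onh_r)
  onh_roi <- lesion_roi("ONH", "ONH", vertices = onh_poly)
  onh_mask <- rasterize_roi(onh_roi, c(h, w))

  lesions <- spec$lesions
  lesion_rois <- lapply(seq_len(nrow(lesions)), function(i) {
    L <- lesions[i, ]
    cc <- mag(c(L$cx, L$cy))
    lesion_roi(L$lesion_id, L$role,
               vertices = regular_ellipse_polygon(cc[1], cc[2], L$rx * m, L$ry * m))
  })
  lesion_masks <- lapply(lesion_rois, rasterize_roi, frame_shape = c(h, w))
  names(lesion_masks) <- lesions$lesion_id

  mottle <- render_mottle(h, w, spec$mottle_scale * m, spec$mottle_amplitude)
  vessel_mask <- render_vessel_tree(h, w, onh_c, spec$n_vessels, onh_r, m)

  # static (time-independent) per-compartment contrast fields
  bg_field <- (spec$background_grey - spec$base_floor) + mottle
  halo_fields <- vector("list", nrow(lesions))
  for (i in seq_len(nrow(lesions))) {
    L <- lesions[i, ]
    if (L$halo_width > 0) {
      cc <- mag(c(L$cx, L$cy)); rx <- L$rx * m; ry <- L$ry * m
      ext <- 3 * L$halo_width * m
      xr <- max(0, floor(cc[1] - rx - ext)):min(w - 1, ceiling(cc[1] + rx + ext))
      yr <- max(0, floor(cc[2] - ry - ext)):min(h - 1, ceiling(cc[2] + ry + ext))
      dx <- matrix((xr - cc[1]) / rx, length(yr), length(xr), byrow = TRUE)
      dy <- matrix((yr - cc[2]) / ry, length(yr), length(xr))
      rho <- sqrt(dx^2 + dy^2)
      r_eff <- sqrt(rx * ry)
      halo <- exp(-((pmax(rho - 1, 0) * r_eff) / (L$halo_width * m))^2)
      halo[rho <= 1] <- 0  # inside the border the lesion field applies
      halo_fields[[i]] <- list(xr = xr, yr = yr, field = halo * L$delta_grey)
    }
  }

  # decoy red/blue channels: static structured content, never the signal
  decoy_r <- matrix(round(15 + 6 * sin(seq_len(w) / 17)), h, w, byrow = TRUE) +
    matrix(sample(0:2, h * w, replace = TRUE), h, w)
  decoy_b <- matrix(round(12 + 5 * cos(seq_len(h) / 23)), h, w) +
    matrix(sample(0:2, h * w, replace = TRUE), h, w)

  maxv <- 2^spec$bit_depth - 1
  wend <- max(spec$times, 600)
  kw <- function(comp, t) kinetic_weight(t, spec$route, comp, window_end = wend)

  frames <- vector("list", length(spec$times))
  for (fi in seq_along(spec$times)) {
    t <- spec$times[fi]
    g <- matrix(spec$base_floor, h, w)
    g <- g + bg_field * kw("choroid", t)
    g[vessel_mask] <- g[vessel_mask] + spec$vessel_grey * kw("vessel", t)
    g[onh_mask] <- g[onh_mask] + spec$vessel_grey * 0.6 * kw("onh", t)
    k_les <- kw("lesion", t)
    for (i in seq_len(nrow(lesions))) {
      msk <- lesion_masks[[i]]
      g[msk] <- g[msk] + lesions$delta_grey[i] * k_les
      hf <- halo_fields[[i]]
      if (!is.null(hf)) {
        sub <- g[hf$yr + 1L, hf$xr + 1L]
        g[hf$yr + 1L, hf$xr + 1L] <- sub + hf$field * k_les
      }
    }
    if (spec$noise_sd > 0) g <- g + rnorm(h * w, 0, spec$noise_sd)
    g <- pmin(pmax(round(g), 0), maxv)
    fr <- array(0, dim = c(h, w, 3))
    fr[, , 1] <- pmin(decoy_r, maxv); fr[, , 2] <- g; fr[, , 3] <- pmin(decoy_b, maxv)
    frames[[fi]] <- fr
  }

  rois <- roi_set(c(lesion_rois, list(onh_roi),
                    list(lesion_roi("vessels", "vessel", mask = vessel_mask))))
  onh_area <- sum(onh_mask)
  areas <- vapply(lesion_masks, sum, 0L)
  truth <- list(
    lesion_masks = lesion_masks, onh_mask = onh_mask, vessel_mask = vessel_mask,
    lesion_areas_px = areas, onh_area_px = onh_area,
    normalized_areas = areas / onh_area,
    delta_grey = setNames(lesions$delta_grey, lesions$lesion_id),
    roles = setNames(lesions$role, lesions$lesion_id),
    kinetics = if (spec$route == "IV") IV_KINETICS else IP_KINETICS,
    route = spec$route, times = spec$times, magnification = m, seed = spec$seed
  )
  list(sequence = frame_sequence(frames, spec$times, spec$bit_depth),
       rois = rois, truth = truth)
}

#' Simulate a bare time-intensity trace
#'
#' Generates a lesion trace directly from a kinetic curve (no image
#' rendering): baseline + curve + Gaussian noise on the given timestamps.
#'
#' @param times Timestamps (seconds).
#' @param route `"IV"` (gamma-variate) or `"IP"` (logarithmic rise).
#' @param A,t0,theta,alpha Gamma-variate parameters (IV).
#' @param tau Rise time-scale (IP).
#' @param baseline Baseline grey level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param lesion_id Identifier carried on the trace.
#' @return An `ffa_trace` tibble; the true parameters are attached as
#'   attribute `"truth"`.
#' @export
simulate_trace <- function(times, route = c("IV", "IP"), A = 120, t0 = 7,
                           theta = 3.2, alpha = 2, tau = 40, baseline = 12,
                           noise_sd = 0, seed = 1L, lesion_id = "sim") {
  route <- match.arg(route)
  seed_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  curve <- if (route == "IV") gamma_variate(times, A, t0, theta, alpha)
           else log_rise(times, A, t0, tau)
  vals <- baseline + curve + rnorm(length(times), 0, noise_sd)
  tr <- new_trace(times, vals, lesion_id)
  attr(tr, "truth") <- list(route = route, A = A, t0 = t0, theta = theta,
                            alpha = alpha, tau = tau, baseline = baseline,
                            noise_sd = noise_sd)
  tr
}

#' Generate a two-group phantom cohort
#'
#' Emulates the treatment study design: each animal's lasered eye carries
#' several lesions; one group receives a treatment programmed to shrink
#' normalized lesion area and net fluorescence by the given effects. Each
#' eye gets its own magnification factor and scene seed, and each lesion
#' draws its size and contrast from the group distribution.
#'
#' @param n_per_group Eyes per group (>= 2); the study used 16.
#' @param effect List with `area_ratio` and `net`: additive differences in
#'   the treated group's mean normalized area and mean net fluorescence
#'   (negative = inhibition). Default mirrors a strong anti-VEGF response.
#' @param groups Character vector of two group labels.
#' @param lesions_per_eye Lesions per eye (a count or range to sample from).
#' @param week Study week recorded in the manifest.
#' @param width,height,noise_sd,mottle_amplitude Scene parameters passed to
#'   [scene_spec()].
#' @param seed Integer master seed.
#' @return List of class `phantom_cohort`: `scenes` (named list of
#'   [generate_scene()] outputs), `manifest` (tibble: animal_id, eye,
#'   group, week, route, lesion_id), `truth` (tibble of per-lesion ground
#'   truth), `effect`, `seed`.
#' @export
generate_cohort <- function(n_per_group = 16, effect = list(area_ratio = -0.6, net = -20),
                            groups = c("PBS", "anti-VEGF"),
                            lesions_per_eye = 3:4, week = 2,
                            width = 1024, height = 768,
                            noise_sd = 2, mottle_amplitude = 4, seed = 1L) {
  stopifnot(n_per_group >= 2, length(groups) == 2)
  seed_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  scale <- min(width / 1024, height / 768)  # all scene lengths scale together
  onh_r <- 48 * scale
  base_ratio <- 2.0; ratio_sd <- 0.35       # PBS normalized-area distribution
  base_net <- 60; net_sd <- 8               # PBS net-fluorescence distribution

  scenes <- list(); manifest <- list(); truth_rows <- list()
  aid <- 0L
  for (gi in seq_along(groups)) {
    d_ratio <- if (gi == 2) effect$area_ratio else 0
    d_net <- if (gi == 2) effect$net else 0
    for (k in seq_len(n_per_group)) {
      aid <- aid + 1L
      animal <- sprintf("R%02d", aid)
      n_les <- if (length(lesions_per_eye) > 1) sample(lesions_per_eye, 1) else lesions_per_eye
      ratio <- pmax(rnorm(n_les, base_ratio + d_ratio, ratio_sd), 0.4)
      net <- pmax(rnorm(n_les, base_net + d_net, net_sd), 5)
      ang <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n_les) - 1) / n_les
      dist <- runif(n_les, 2.1, 2.9) * 2 * onh_r
      r_les <- onh_r * sqrt(ratio)
      ecc <- runif(n_les, 0.9, 1.1)
      onh_cx <- width * 0.42; onh_cy <- height * 0.5
      les <- tibble(
        lesion_id = sprintf("%s_L%d", animal, seq_len(n_les)),
        role = "CNV",
        cx = onh_cx + dist * cos(ang), cy = onh_cy + dist * sin(ang),
        rx = r_les * ecc, ry = r_les / ecc,
        delta_grey = round(net), halo_width = 6 * scale
      )
      spec <- scene_spec(
        width = width, height = height,
        onh_center = c(onh_cx, onh_cy), onh_radius = onh_r,
        lesions = les, route = "IV", times = 10.2,
        magnification = runif(1, 0.9, 1.15),
        noise_sd = noise_sd, mottle_amplitude = mottle_amplitude,
        seed = sample.int(2^30, 1)
      )
      sc <- generate_scene(spec)
      eye_id <- sprintf("%s_OS", animal)
      scenes[[eye_id]] <- sc
      manifest[[eye_id]] <- tibble(
        animal_id = animal, eye = "OS", group = groups[gi], week = week,
        route = "IV", lesion_id = les$lesion_id
      )
      truth_rows[[eye_id]] <- tibble(
        lesion_id = les$lesion_id, group = groups[gi],
        true_normalized_area = unname(sc$truth$normalized_areas[les$lesion_id]),
        true_net = les$delta_grey,
        magnification = spec$magnification
      )
    }
  }
  structure(
    list(scenes = scenes, manifest = dplyr::bind_rows(manifest),
         truth = dplyr::bind_rows(truth_rows), effect = effect,
         groups = groups, seed = as.integer(seed)),
    class = "phantom_cohort"
  )
}

#' Render a synthetic choroidal flatmount micrograph
#'
#' A fluorescence-like single-channel image: dark field, bright isolectin-
#' stained lesion, and an embedded horizontal scale bar of recorded length.
#'
#' @param area_um2 Target lesion area in square micrometres (a disc of this
#'   area is drawn), or `NULL` when `vertices` is given.
#' @param vertices Optional lesion polygon (pixel coordinates).
#' @param um_per_px Micrometres per pixel (> 0).
#' @param width,height Image dimensions (pixels).
#' @param scale_bar_um Physical scale-bar length (micrometres).
#' @param lesion_grey,field_grey,noise_sd Rendering parameters (8-bit grey).
#' @param seed Integer seed for the noise.
#' @return List: `image` (matrix), `scale_bar` (list with `length_px`,
#'   `length_um`, `row`, `col`), `truth_area_um2` (rasterized lesion area
#'   converted through `um_per_px`), `lesion_mask`, `um_per_px`.
#' @export
render_flatmount <- function(area_um2 = 146951, vertices = NULL, um_per_px = 1.5,
                             width = 1360, height = 1024, scale_bar_um = 500,
                             lesion_grey = 180, field_grey = 25, noise_sd = 3,
                             seed = 1L) {
  if (um_per_px <= 0) stop_data("um_per_px must be positive")
  seed_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  if (is.null(vertices)) {
    r_px <- sqrt(area_um2 / pi) / um_per_px
    vertices <- regular_ellipse_polygon(width / 2, height / 2, r_px, r_px, n = 96)
  }
  roi <- lesion_roi("FM1", "CNV", vertices = vertices)
  mask <- rasterize_roi(roi, c(height, width))
  img <- matrix(field_grey, height, width)
  img[mask] <- lesion_grey
  if (noise_sd > 0) img <- img + rnorm(height * width, 0, noise_sd)
  img <- pmin(pmax(round(img), 0), 255)
  # scale bar: shrink to fit small fields, keeping the recorded length honest
  bar_px <- round(scale_bar_um / um_per_px)
  bar_col <- max(10L, round(width * 0.03))
  if (bar_col + bar_px - 1L > width) {
    bar_px <- as.integer(width - 2L * bar_col)
    scale_bar_um <- bar_px * um_per_px
  }
  bar_row <- max(1L, height - max(10L, round(height * 0.04)))
  rows <- bar_row:min(bar_row + 5L, height)
  img[rows, bar_col:(bar_col + bar_px - 1L)] <- 255
  list(image = img,
       scale_bar = list(length_px = bar_px, length_um = scale_bar_um,
                        row = bar_row, col = bar_col),
       truth_area_um2 = sum(mask) * um_per_px^2,
       lesion_mask = mask, um_per_px = um_per_px)
}
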