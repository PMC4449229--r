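# Shared fixtures and independent oracles, built in code at test time.

# regular n-gon approximation of a circle/ellipse
disc_polygon <- function(cx, cy, r, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_polygon <- function(cx, cy, rx, ry, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + rx * cos(th), y = cy + ry * sin(th))
}

# Brute-force even-odd point-in-polygon: per-pixel loop, crossing count
# computed edge by edge. Independent of the package's vectorized
# implementation; only usable for small frames.
pip_oracle_point <- function(px, py, vx, vy) {
  n <- length(vx)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    y1 <- vy[i]; y2 <- vy[j]
    if ((y1 > py) != (y2 > py)) {
      xint <- vx[i] + (py - y1) * (vx[j] - vx[i]) / (y2 - y1)
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

rasterize_oracle <- function(vertices, frame_shape) {
  h <- frame_shape[1]; w <- frame_shape[2]
  m <- matrix(FALSE, h, w)
  for (y in 0:(h - 1)) {
    for (x in 0:(w - 1)) {
      m[y + 1, x + 1] <- pip_oracle_point(x, y, vertices[, 1], vertices[, 2])
    }
  }
  m
}

# small single-lesion scene used across tests
small_scene <- function(delta = 60, role = "CNV", halo = 0, noise = 0,
                        mottle = 0, magnification = 1, seed = 1L,
                        times = 10.2, lesion_r = 30, n_vessels = 4) {
  spec <- scene_spec(
    width = 360, height = 280,
    onh_center = c(110, 140), onh_radius = 26,
    n_vessels = n_vessels,
    lesions = tibble::tibble(
      lesion_id = "L1", role = role, cx = 255, cy = 140,
      rx = lesion_r, ry = lesion_r * 0.95,
      delta_grey = delta, halo_width = halo),
    route = "IV", times = times,
    magnification = magnification,
    mottle_amplitude = mottle, noise_sd = noise, seed = seed)
  generate_scene(spec)
}
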