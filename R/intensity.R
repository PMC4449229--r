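# Intensity measurements: lesion mean grey, annulus background estimate from
# six vessel-free patches, net fluorescence and the area-corrected score.
# All grey arithmetic is carried out in floating point; intermediate values
# are never clamped back to the acquisition bit depth.

#' Mean grey value over a lesion, vessels excluded
#'
#' Large vessels crossing a hyperfluorescent lesion contribute their own
#' fluorescence and are excluded from the lesion mean.
#'
#' @param frame Numeric grey matrix.
#' @param lesion_mask Logical matrix of lesion pixels.
#' @param vessel_mask Optional logical matrix of vessel pixels to exclude.
#' @param lesion_id Identifier used in error messages.
#' @return Mean grey value (double).
#' @export
lesion_mean_grey <- function(frame, lesion_mask, vessel_mask = NULL,
                             lesion_id = NULL) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(lesion_mask)))
  keep <- lesion_mask
  if (!is.null(vessel_mask)) {
    stopifnot(identical(dim(frame), dim(vessel_mask)))
    keep <- keep & !vessel_mask
  }
  if (!any(keep)) {
    stop_unquantifiable(
      sprintf("lesion%s is entirely covered by the vessel mask",
              if (is.null(lesion_id)) "" else sprintf(" '%s'", lesion_id)),
      lesion_id = lesion_id)
  }
  mean(frame[keep])
}

default_patch_side <- function(lesion_area_px) {
  max(5L, as.integer(round(sqrt(lesion_area_px / pi) / 6)))
}

#' Estimate local background from six annulus patches
#'
#' Background fluorescence local to a lesion is the mean of six square,
#' vessel-free patches inside the background annulus. The graders of the
#' original workflow picked "representative" patches by eye; here the choice
#' is deterministic and reproducible: every annulus pixel whose full square
#' patch fits inside the vessel-free annulus is a candidate patch centre;
#' candidates are ranked by angular position about the lesion centroid and
#' six are picked greedily at target angles 60 degrees apart (random
#' starting angle and tie-breaks from the seeded RNG), maximizing angular
#' spread around the lesion much as a human grader would.
#'
#' @param frame Numeric grey matrix.
#' @param annulus An [build_annulus()] result.
#' @param vessel_mask Optional logical matrix of vessel pixels.
#' @param patch_side Patch side length in pixels; default
#'   `max(5, round(lesion_equivalent_radius / 6))`.
#' @param seed Integer seed for the tie-breaking RNG.
#' @param lesion_id Identifier used in error messages.
#' @return Object of class `background_estimate`: list with `patch_centers`
#'   (tibble of x, y), `patch_side`, `patch_means`, `background_mean`.
#' @export
sample_background <- function(frame, annulus, vessel_mask = NULL,
                              patch_side = NULL, seed = 1L, lesion_id = NULL) {
  stopifnot(inherits(annulus, "annulus_region"),
            identical(dim(frame), dim(annulus$mask)))
  s <- patch_side %||% default_patch_side(sum(annulus$lesion_mask))
  s <- as.integer(s)
  stopifnot(s >= 1)
  allowed <- annulus$mask
  if (!is.null(vessel_mask)) {
    stopifnot(identical(dim(frame), dim(vessel_mask)))
    allowed <- allowed & !vessel_mask
  }
  if (sum(allowed) < 6 * s^2) {
    stop_unquantifiable(
      sprintf("lesion%s: annulus has %d vessel-free pixels, need >= %d for 6 patches of side %d",
              if (is.null(lesion_id)) "" else sprintf(" '%s'", lesion_id),
              sum(allowed), 6L * s^2, s),
      lesion_id = lesion_id)
  }

  # candidate centres: the full s x s patch lies inside the allowed region
  off_lo <- -((s - 1L) %/% 2L)
  off_hi <- s %/% 2L
  fits <- box_sums(allowed * 1, off_lo, off_hi) == s^2
  fits <- fits & allowed
  cand <- which(fits, arr.ind = TRUE)
  if (nrow(cand) < 6) {
    stop_unquantifiable(
      sprintf("lesion%s: only %d candidate background patch positions",
              if (is.null(lesion_id)) "" else sprintf(" '%s'", lesion_id), nrow(cand)),
      lesion_id = lesion_id)
  }
  cx <- cand[, 2] - 1; cy <- cand[, 1] - 1
  ang <- (atan2(cy - annulus$centroid["y"], cx - annulus$centroid["x"]) * 180 / pi) %% 360

  # seeded, self-contained RNG use: the caller's RNG state is untouched
  seed_state <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  start <- runif(1, 0, 60)
  tie <- runif(length(ang))

  targets <- (start + (0:5) * 60) %% 360
  picked <- integer(0)
  for (tgt in targets) {
    d <- ang_dist(ang, tgt)
    ord <- order(d, tie)                # seeded tie-break among equal angles
    sel <- NA_integer_
    for (i in ord) {
      if (length(picked) == 0 ||
          all(pmax(abs(cx[i] - cx[picked]), abs(cy[i] - cy[picked])) >= s)) {
        sel <- i; break
      }
    }
    if (is.na(sel)) {
      stop_unquantifiable(
        sprintf("lesion%s: cannot place 6 disjoint background patches",
                if (is.null(lesion_id)) "" else sprintf(" '%s'", lesion_id)),
        lesion_id = lesion_id)
    }
    picked <- c(picked, sel)
  }

  patch_means <- vapply(picked, function(i) {
    rows <- (cy[i] + off_lo):(cy[i] + off_hi) + 1L
    cols <- (cx[i] + off_lo):(cx[i] + off_hi) + 1L
    mean(frame[rows, cols])
  }, 0)

  # hard guarantees: patches inside annulus, off vessels, off the lesion
  for (i in picked) {
    rows <- (cy[i] + off_lo):(cy[i] + off_hi) + 1L
    cols <- (cx[i] + off_lo):(cx[i] + off_hi) + 1L
    stopifnot(all(allowed[rows, cols]), !any(annulus$lesion_mask[rows, cols]))
  }

  structure(
    list(patch_centers = tibble(x = cx[picked], y = cy[picked]),
         patch_side = s, patch_means = patch_means,
         background_mean = mean(patch_means)),
    class = "background_estimate"
  )
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate: 6 patches of side %d, mean grey %.2f>\n",
              x$patch_side, x$background_mean))
  invisible(x)
}

#' Net fluorescence above local background
#'
#' Lesion mean grey minus the annulus background mean. Negative values are
#' meaningful: avascular chorio-retinal burns are hypofluorescent and sit
#' below their background.
#'
#' @param lesion_mean Lesion mean grey value.
#' @param background_mean Background mean grey value.
#' @return Net grey value (double, may be negative).
#' @export
net_fluorescence <- function(lesion_mean, background_mean) {
  stopifnot(is.finite(lesion_mean), is.finite(background_mean))
  lesion_mean - background_mean
}

#' Area-corrected lesion intensity
#'
#' The composite severity score: net fluorescence multiplied by the
#' ONH-normalized lesion area. It amounts to the summed grey value within
#' the lesion border, above background, expressed in optic-nerve-head area
#' units, and combines vessel leakiness (intensity) with anatomical extent
#' (area) in a single number.
#'
#' @param net Net fluorescence (grey levels, may be negative).
#' @param normalized_area ONH-normalized lesion area (> 0).
#' @return The product (double).
#' @export
area_corrected_intensity <- function(net, normalized_area) {
  stopifnot(all(normalized_area > 0))
  net * normalized_area
}

#' Convert a flatmount lesion area from pixels to square micrometres
#'
#' Choroidal flatmount micrographs carry a scale bar; the pixel area of an
#' outlined lesion converts to micrometres squared through the bar's
#' pixel-per-micrometre ratio.
#'
#' @param area_px Lesion area in pixels.
#' @param scale_bar_px Measured scale-bar length in pixels (> 0).
#' @param scale_bar_um Physical scale-bar length in micrometres (> 0).
#' @return Area in square micrometres.
#' @export
flatmount_area_um2 <- function(area_px, scale_bar_px, scale_bar_um) {
  if (any(scale_bar_px <= 0) || any(scale_bar_um <= 0)) {
    stop_data("scale bar lengths must be positive")
  }
  area_px * (scale_bar_um / scale_bar_px)^2
}
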