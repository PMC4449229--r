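# ROI containers and raster geometry.
#
# Coordinate convention used throughout the package: x = column, y = row,
# both 0-based, with pixel centres at integer coordinates (top-left pixel
# centre is (0, 0)). Masks are logical matrices indexed mask[y + 1, x + 1].
# Polygons are rasterized with even-odd fill; a pixel belongs to the polygon
# when its centre lies inside under the even-odd (crossing-number) rule.

ROI_ROLES <- c("CNV", "CR_burn", "ONH", "vessel")

#' Construct a lesion ROI
#'
#' An ROI is a named region drawn on a fundus frame: a hyperfluorescent CNV
#' lesion, a hypofluorescent chorio-retinal burn, the optic nerve head used
#' as the anatomical magnification ruler, or a vessel region to exclude from
#' intensity measurements. The geometry is either a polygon (vertex matrix,
#' the usual output of freehand outlining) or a binary mask.
#'
#' @param lesion_id Character identifier, unique within a role.
#' @param role One of `"CNV"`, `"CR_burn"`, `"ONH"`, `"vessel"`.
#' @param vertices Numeric n x 2 matrix of (x, y) vertex coordinates
#'   (0-based, pixel-centre convention), n >= 3. Exactly one of `vertices`
#'   and `mask` must be supplied.
#' @param mask Logical matrix (rows = y, columns = x) marking member pixels.
#' @return An object of class `lesion_roi`.
#' @export
lesion_roi <- function(lesion_id, role, vertices = NULL, mask = NULL) {
  role <- match.arg(role, ROI_ROLES)
  if (is.null(vertices) == is.null(mask)) {
    stop_data("supply exactly one of `vertices` or `mask`")
  }
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2 || nrow(vertices) < 3) {
      stop_data(sprintf("ROI '%s': a polygon needs >= 3 (x, y) vertices", lesion_id))
    }
    storage.mode(vertices) <- "double"
    colnames(vertices) <- c("x", "y")
    geom <- "polygon"
  } else {
    mask <- mask != 0
    if (!any(mask)) stop_data(sprintf("ROI '%s': empty mask", lesion_id))
    geom <- "mask"
  }
  structure(
    list(lesion_id = as.character(lesion_id), role = role,
         geometry = geom, vertices = vertices, mask = mask),
    class = "lesion_roi"
  )
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("<lesion_roi '%s' role=%s geometry=%s>\n",
              x$lesion_id, x$role, x$geometry))
  invisible(x)
}

#' Bundle ROIs into a set
#'
#' @param rois List of [lesion_roi()] objects.
#' @param source_dialect Where the set came from: `"polygon-json"`,
#'   `"imagej-roi"`, `"mask-image"` or `"memory"`.
#' @return An object of class `roi_set` (a list with elements `rois` and
#'   `source_dialect`).
#' @export
roi_set <- function(rois, source_dialect = "memory") {
  stopifnot(is.list(rois))
  rois <- unname(rois)
  for (r in rois) {
    if (!inherits(r, "lesion_roi")) stop_data("all elements must be lesion_roi objects")
  }
  key <- vapply(rois, function(r) paste(r$role, r$lesion_id), "")
  if (anyDuplicated(key)) {
    stop_data(sprintf("duplicate (role, lesion_id): %s", key[duplicated(key)][1]))
  }
  structure(list(rois = rois, source_dialect = source_dialect), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set of %d ROIs (%s)>\n", length(x$rois), x$source_dialect))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$rois)

#' Retrieve ROIs of one role from a set
#'
#' @param rois A [roi_set()].
#' @param role Role to filter on.
#' @return List of `lesion_roi` objects (possibly empty).
#' @export
rois_by_role <- function(rois, role) {
  role <- match.arg(role, ROI_ROLES)
  Filter(function(r) r$role == role, rois$rois)
}

# Even-odd point-in-polygon test, vectorized over query points.
# px, py: query pixel centres; vx, vy: polygon vertices (closed implicitly).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]; xi <- vx[i]; xj <- vx[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

# Rasterize a polygon over an arbitrary integer pixel range (may extend
# outside the frame). Returns an integer matrix of (x, y) pixel coordinates.
rasterize_polygon_pixels <- function(vertices, xlim = NULL, ylim = NULL) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  xr <- c(ceiling(min(vx)), floor(max(vx)))
  yr <- c(ceiling(min(vy)), floor(max(vy)))
  if (!is.null(xlim)) xr <- c(max(xr[1], xlim[1]), min(xr[2], xlim[2]))
  if (!is.null(ylim)) yr <- c(max(yr[1], ylim[1]), min(yr[2], ylim[2]))
  if (xr[2] < xr[1] || yr[2] < yr[1]) {
    return(cbind(x = integer(0), y = integer(0)))
  }
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  keep <- point_in_polygon(px, py, vx, vy)
  cbind(x = px[keep], y = py[keep])
}

#' Rasterize an ROI to a pixel mask
#'
#' Converts the ROI geometry to a logical mask of the given frame shape.
#' Polygons are filled under the even-odd rule evaluated at pixel centres
#' (0-based integer coordinates); mask geometries are cropped/padded to the
#' frame shape.
#'
#' @param roi A [lesion_roi()].
#' @param frame_shape Integer `c(height, width)` of the target frame.
#' @return Logical matrix `frame_shape[1]` x `frame_shape[2]`.
#' @export
rasterize_roi <- function(roi, frame_shape) {
  stopifnot(inherits(roi, "lesion_roi"), length(frame_shape) == 2,
            all(frame_shape >= 1))
  h <- as.integer(frame_shape[1]); w <- as.integer(frame_shape[2])
  m <- matrix(FALSE, h, w)
  if (roi$geometry == "mask") {
    src <- roi$mask
    rr <- seq_len(min(h, nrow(src))); cc <- seq_len(min(w, ncol(src)))
    m[rr, cc] <- src[rr, cc]
  } else {
    px <- rasterize_polygon_pixels(roi$vertices, xlim = c(0L, w - 1L),
                                   ylim = c(0L, h - 1L))
    m[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- TRUE
  }
  if (!any(m)) {
    stop_data(sprintf("ROI '%s' rasterizes to an empty mask within the frame",
                      roi$lesion_id))
  }
  m
}

#' Pixel area of an ROI
#'
#' @inheritParams rasterize_roi
#' @return Integer pixel count of the rasterized ROI.
#' @export
roi_area_px <- function(roi, frame_shape) sum(rasterize_roi(roi, frame_shape))

# centroid (x, y) of a logical mask, in pixel-centre coordinates
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' Build the background annulus around a lesion
#'
#' The local background of a lesion is sampled from an annulus whose inner
#' border is the lesion's own outer border and whose outer border has twice
#' the radius of the inner border. For arbitrary (non-circular) outlines the
#' outer border is the inner border scaled by `scale` about the lesion
#' centroid, which reduces to the twice-the-radius rule for circles and
#' keeps the ring shape-following for elongated lesions. Annulus pixels
#' falling outside the frame are dropped and reported as `clip_fraction`.
#'
#' @param lesion A [lesion_roi()] with role `"CNV"` or `"CR_burn"`.
#' @param frame_shape Integer `c(height, width)`.
#' @param scale Linear scale factor of the outer border about the centroid
#'   (default 2, the twice-the-radius rule).
#' @return An object of class `annulus_region`: list with `mask` (in-frame
#'   annulus pixels, disjoint from the lesion), `lesion_mask`, `centroid`,
#'   `clip_fraction` and `scale`.
#' @export
build_annulus <- function(lesion, frame_shape, scale = 2) {
  stopifnot(inherits(lesion, "lesion_roi"), scale > 1)
  if (!lesion$role %in% c("CNV", "CR_burn")) {
    stop_data(sprintf("annulus is defined for CNV/CR_burn lesions, not role '%s'",
                      lesion$role))
  }
  h <- as.integer(frame_shape[1]); w <- as.integer(frame_shape[2])
  lesion_mask <- rasterize_roi(lesion, frame_shape)
  ctr <- mask_centroid(lesion_mask)

  if (lesion$geometry == "polygon") {
    outer_v <- sweep(sweep(lesion$vertices, 2, ctr, "-") * scale, 2, ctr, "+")
    outer_px <- rasterize_polygon_pixels(outer_v)           # unclipped plane
  } else {
    # preimage test: p is inside the scaled region iff c + (p - c)/scale,
    # rounded to the nearest pixel centre, is a member of the lesion mask
    idx <- which(lesion_mask, arr.ind = TRUE)
    x0 <- range(idx[, 2] - 1); y0 <- range(idx[, 1] - 1)
    xs <- floor(ctr["x"] + scale * (x0[1] - ctr["x"])):ceiling(ctr["x"] + scale * (x0[2] - ctr["x"]))
    ys <- floor(ctr["y"] + scale * (y0[1] - ctr["y"])):ceiling(ctr["y"] + scale * (y0[2] - ctr["y"]))
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    qx <- round(ctr["x"] + (px - ctr["x"]) / scale)
    qy <- round(ctr["y"] + (py - ctr["y"]) / scale)
    ok <- qx >= 0 & qx < ncol(lesion_mask) & qy >= 0 & qy < nrow(lesion_mask)
    ok[ok] <- lesion_mask[cbind(qy[ok] + 1L, qx[ok] + 1L)]
    outer_px <- cbind(x = px[ok], y = py[ok])
  }

  inframe <- outer_px[, "x"] >= 0 & outer_px[, "x"] < w &
    outer_px[, "y"] >= 0 & outer_px[, "y"] < h
  outer_mask <- matrix(FALSE, h, w)
  outer_mask[cbind(outer_px[inframe, "y"] + 1L, outer_px[inframe, "x"] + 1L)] <- TRUE

  ann_mask <- outer_mask & !lesion_mask
  # pixels lost to clipping, relative to the annulus on the unbounded plane
  n_total <- nrow(outer_px) - sum(lesion_mask)
  n_kept <- sum(ann_mask)
  if (n_kept == 0) {
    stop_unquantifiable(
      sprintf("annulus of lesion '%s' is entirely outside the frame", lesion$lesion_id),
      lesion_id = lesion$lesion_id
    )
  }
  stopifnot(!any(ann_mask & lesion_mask))  # disjoint by construction
  structure(
    list(mask = ann_mask, lesion_mask = lesion_mask, centroid = ctr,
         clip_fraction = 1 - n_kept / n_total, scale = scale),
    class = "annulus_region"
  )
}

#' @export
print.annulus_region <- function(x, ...) {
  cat(sprintf("<annulus_region: %d px, clip_fraction=%.3f, scale=%.1f>\n",
              sum(x$mask), x$clip_fraction, x$scale))
  invisible(x)
}

#' Normalize a lesion area against the optic nerve head
#'
#' Contact of the camera lens with the cornea magnifies the fundus image by
#' a per-session factor. Dividing the lesion pixel area by the session's
#' mean optic nerve head pixel area cancels this magnification, because both
#' areas scale with its square.
#'
#' @param lesion_area_px Lesion area in pixels (> 0).
#' @param onh_areas_px Numeric vector of ONH pixel areas for the session
#'   (several outlines/frames may contribute); all > 0.
#' @return Dimensionless normalized area (lesion / mean ONH).
#' @export
normalize_area <- function(lesion_area_px, onh_areas_px) {
  if (length(onh_areas_px) == 0 || any(!is.finite(onh_areas_px)) ||
      any(onh_areas_px <= 0)) {
    stop_data("ONH areas must be a non-empty vector of positive values")
  }
  if (any(lesion_area_px <= 0)) stop_data("lesion area must be positive")
  lesion_area_px / mean(onh_areas_px)
}
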