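# Frame-sequence container, acquisition schedules and TIFF / ROI file I/O.

#' Construct a frame sequence
#'
#' An ordered set of fundus frames bound to acquisition times. Frames are
#' integer grey rasters (matrices) or RGB arrays (h x w x 3) at native bit
#' depth; timestamps are seconds since the start of the fluorescein bolus,
#' with t = 0 at the first captured frame.
#'
#' @param frames List of numeric matrices (grey) or h x w x 3 arrays (RGB),
#'   all of identical dimensions, values in `[0, 2^bit_depth - 1]`.
#' @param times Numeric vector of per-frame timestamps (seconds), strictly
#'   increasing, same length as `frames`.
#' @param bit_depth Bits per channel (default 8, i.e. 24-bit RGB).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, times, bit_depth = 8L) {
  if (!is.list(frames) || length(frames) == 0) stop_format("`frames` must be a non-empty list")
  if (length(times) != length(frames)) stop_schedule("one timestamp per frame required")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_schedule("timestamps must be strictly increasing")
  }
  d0 <- dim(frames[[1]])
  maxv <- 2^bit_depth - 1
  for (i in seq_along(frames)) {
    d <- dim(frames[[i]])
    if (length(d) != length(d0) || any(d != d0)) {
      stop_format(sprintf("frame %d has dimensions %s, expected %s",
                          i, paste(d, collapse = "x"), paste(d0, collapse = "x")))
    }
    rng <- range(frames[[i]])
    if (rng[1] < 0 || rng[2] > maxv) {
      stop_format(sprintf("frame %d has grey values outside [0, %d]", i, maxv))
    }
  }
  structure(
    list(frames = frames, times = as.double(times), bit_depth = as.integer(bit_depth)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence: %d frames, %dx%d, %d channel(s), %d-bit, t=[%.3f, %.3f] s>\n",
              length(x$frames), d[2], d[1], n_channels(x), x$bit_depth,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Number of colour channels in a frame sequence
#' @param seq A [frame_sequence()].
#' @return 1 for grey sequences, 3 for RGB.
#' @export
n_channels <- function(seq) {
  d <- dim(seq$frames[[1]])
  if (length(d) == 2) 1L else d[3]
}

#' Frame height/width
#' @param seq A [frame_sequence()].
#' @return Integer `c(height, width)`.
#' @export
frame_shape <- function(seq) dim(seq$frames[[1]])[1:2]

#' Timestamps for a piecewise-constant acquisition schedule
#'
#' Builds the per-frame timestamp vector for a capture schedule given as
#' one or more (rate, duration) segments, with the first frame at t = 0.
#' A segment at rate r frames/s spanning d seconds contributes r*d frames
#' at intervals 1/r starting at the segment start.
#'
#' @param rates Frames per second, one per segment.
#' @param durations Segment durations in seconds, one per segment.
#' @return Numeric vector of timestamps (seconds).
#' @examples
#' # intraperitoneal schedule: 1 fps for 120 s, then 1 frame / 5 s to 10 min
#' t_ip <- schedule_times(c(1, 0.2), c(120, 480))
#' length(t_ip)  # 216
#' @export
schedule_times <- function(rates, durations) {
  if (length(rates) != length(durations) || length(rates) == 0) {
    stop_schedule("`rates` and `durations` must be non-empty and equal length")
  }
  if (any(rates <= 0) || any(durations <= 0)) stop_schedule("rates and durations must be positive")
  starts <- cumsum(c(0, head(durations, -1)))
  unlist(Map(function(r, d, s) {
    n <- round(r * d)
    s + (seq_len(n) - 1) / r
  }, rates, durations, starts), use.names = FALSE)
}

#' Standard intravenous acquisition schedule (30 fps for 120 s)
#' @return Timestamp vector of length 3600.
#' @export
iv_schedule_times <- function() schedule_times(30, 120)

#' Standard intraperitoneal acquisition schedule
#'
#' 1 frame/s for 120 s, then 1 frame per 5 s up to 10 minutes post
#' injection (216 frames, last at 595 s).
#' @return Timestamp vector of length 216.
#' @export
ip_schedule_times <- function() schedule_times(c(1, 0.2), c(120, 480))

# read one TIFF page list from a file, as native-integer arrays
read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    info <- attributes(p)
    bits <- info$bits.per.sample %||% 8L
    v <- round(unclass(p) * (2^bits - 1))
    attr(v, "bits.per.sample") <- as.integer(bits)
    v
  })
}

#' Read a fundus frame sequence from TIFF
#'
#' Reads a multi-page TIFF, or a directory of single-page TIFFs taken in
#' lexicographic filename order, and binds the frames to acquisition times.
#' RGB frames are retained as 3-channel until [extract_green()] is applied.
#'
#' @param path A multi-page TIFF file or a directory of TIFF files.
#' @param times Explicit per-frame timestamps (seconds). Overrides `rates`/
#'   `durations` when given.
#' @param rates,durations Piecewise schedule passed to [schedule_times()];
#'   a single rate with `durations = NULL` means a constant frame rate.
#' @return A [frame_sequence()].
#' @export
read_frame_sequence <- function(path, times = NULL, rates = NULL, durations = NULL) {
  if (!file.exists(path)) stop_format(sprintf("no such file or directory: '%s'", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) stop_format(sprintf("no TIFF files in directory '%s'", path))
    frames <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else {
    frames <- read_tiff_pages(path)
  }
  bits <- attr(frames[[1]], "bits.per.sample") %||% 8L
  frames <- lapply(frames, function(f) { attr(f, "bits.per.sample") <- NULL; f })
  n <- length(frames)
  if (is.null(times)) {
    if (is.null(rates)) stop_schedule("supply `times` or a frame-rate schedule")
    if (is.null(durations)) {
      times <- (seq_len(n) - 1) / rates[1]
    } else {
      times <- schedule_times(rates, durations)
      if (length(times) < n) {
        stop_schedule(sprintf("schedule yields %d timestamps for %d frames",
                              length(times), n))
      }
      times <- times[seq_len(n)]
    }
  } else if (length(times) != n) {
    stop_schedule(sprintf("%d timestamps for %d frames", length(times), n))
  }
  frame_sequence(frames, times, bit_depth = bits)
}

#' Write a frame sequence as a multi-page TIFF
#'
#' Grey values are written bit-exactly at the sequence's bit depth; reading
#' the file back with [read_frame_sequence()] reproduces them.
#'
#' @param seq A [frame_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  maxv <- 2^seq$bit_depth - 1
  tiff::writeTIFF(lapply(seq$frames, function(f) f / maxv),
                  path, bits.per.sample = seq$bit_depth)
  invisible(path)
}

#' Extract the green channel from an RGB sequence
#'
#' All area and intensity measurements are taken from the green channel of
#' the 24-bit RGB capture; the red and blue channels are discarded. Grey
#' values are passed through unmodified -- the capture chain is linear, so
#' no rescaling or gamma is applied. A single-channel input is returned
#' unchanged with a warning.
#'
#' @param seq A [frame_sequence()] with 3 channels.
#' @param channel_order Channel order as stored, `"rgb"` (default) or
#'   `"bgr"` for writers that store blue first.
#' @return Single-channel [frame_sequence()].
#' @export
extract_green <- function(seq, channel_order = c("rgb", "bgr")) {
  stopifnot(inherits(seq, "frame_sequence"))
  channel_order <- match.arg(channel_order)
  nc <- n_channels(seq)
  if (nc == 1) {
    warn("sequence is already single-channel; returning unchanged",
         class = "ffa_already_grey")
    return(seq)
  }
  if (nc != 3) stop_format(sprintf("expected 3 channels, found %d", nc))
  g <- if (channel_order == "rgb") 2L else 2L  # green is the middle channel either way
  frame_sequence(lapply(seq$frames, function(f) f[, , g]),
                 seq$times, bit_depth = seq$bit_depth)
}

# ---- ROI file dialects ------------------------------------------------------

roi_filename <- function(roi) sprintf("%s__%s", roi$lesion_id, roi$role)

parse_roi_filename <- function(fname) {
  base <- sub("\\.[^.]+$", "", basename(fname))
  parts <- strsplit(base, "__", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[2] %in% ROI_ROLES) {
    stop_format(sprintf(
      "ROI filename '%s' must look like <lesion_id>__<role>.<ext> with role in %s",
      fname, paste(ROI_ROLES, collapse = "/")))
  }
  list(lesion_id = parts[1], role = parts[2])
}

#' Read a set of ROIs
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`"json"`}{a sidecar file with schema
#'     `{"rois": [{"lesion_id", "role", "vertices": [[x, y], ...]}, ...]}`,
#'     vertices in the package's 0-based pixel-centre convention;}
#'   \item{`"imagej"`}{a directory of ImageJ `.roi` files (polygon and
#'     freehand subtypes), named `<lesion_id>__<role>.roi`;}
#'   \item{`"mask"`}{a directory of binary PNG masks named
#'     `<lesion_id>__<role>.png`, nonzero = member pixel.}
#' }
#'
#' @param path File (json) or directory (imagej, mask).
#' @param dialect One of `"json"`, `"imagej"`, `"mask"`.
#' @return A [roi_set()].
#' @export
read_roi_set <- function(path, dialect = c("json", "imagej", "mask")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(sprintf("no such path: '%s'", path))
  rois <- switch(dialect,
    json = {
      doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
      if (is.null(doc$rois)) stop_format("JSON ROI file must have a top-level 'rois' array")
      lapply(doc$rois, function(r) {
        v <- do.call(rbind, lapply(r$vertices, unlist))
        lesion_roi(r$lesion_id, r$role, vertices = v)
      })
    },
    imagej = {
      files <- sort(list.files(path, pattern = "\\.roi$", full.names = TRUE))
      if (length(files) == 0) stop_format(sprintf("no .roi files in '%s'", path))
      lapply(files, function(f) {
        meta <- parse_roi_filename(f)
        lesion_roi(meta$lesion_id, meta$role, vertices = read_imagej_roi(f))
      })
    },
    mask = {
      files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
      if (length(files) == 0) stop_format(sprintf("no .png mask files in '%s'", path))
      lapply(files, function(f) {
        meta <- parse_roi_filename(f)
        img <- png::readPNG(f)
        if (length(dim(img)) == 3) img <- img[, , 1]
        lesion_roi(meta$lesion_id, meta$role, mask = img > 0.5)
      })
    }
  )
  roi_set(rois, source_dialect = paste0(
    c(json = "polygon-json", imagej = "imagej-roi", mask = "mask-image")[dialect]))
}

#' Write a set of ROIs
#'
#' Counterpart of [read_roi_set()]; the same dialects are produced. Writing
#' polygon ROIs in the `"mask"` dialect rasterizes them (`frame_shape`
#' required); writing mask ROIs as `"imagej"` is not supported.
#'
#' @param rois A [roi_set()].
#' @param path Output file (json) or directory (imagej, mask).
#' @param dialect One of `"json"`, `"imagej"`, `"mask"`.
#' @param frame_shape `c(height, width)`, required for the mask dialect.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path, dialect = c("json", "imagej", "mask"),
                          frame_shape = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rois, "roi_set"))
  switch(dialect,
    json = {
      doc <- list(rois = lapply(rois$rois, function(r) {
        if (r$geometry != "polygon") {
          stop_format(sprintf("ROI '%s' is a mask; JSON dialect stores polygons", r$lesion_id))
        }
        list(lesion_id = r$lesion_id, role = r$role,
             vertices = lapply(seq_len(nrow(r$vertices)),
                               function(i) unname(r$vertices[i, ])))
      }))
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    },
    imagej = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      for (r in rois$rois) {
        if (r$geometry != "polygon") {
          stop_format(sprintf("ROI '%s' is a mask; ImageJ dialect stores polygons", r$lesion_id))
        }
        write_imagej_roi(r$vertices, file.path(path, paste0(roi_filename(r), ".roi")))
      }
    },
    mask = {
      if (is.null(frame_shape)) stop_format("mask dialect requires `frame_shape`")
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      for (r in rois$rois) {
        m <- rasterize_roi(r, frame_shape)
        png::writePNG(m * 1, file.path(path, paste0(roi_filename(r), ".png")))
      }
    }
  )
  invisible(path)
}

# ---- ImageJ .roi binary dialect --------------------------------------------
#
# Subset of the ImageJ ROI file format handled here (big-endian throughout):
#   bytes 0-3   magic "Iout"
#   bytes 4-5   version (short; we write 227)
#   byte  6     roi type: 0 = polygon, 7 = freehand
#   byte  7     unused
#   bytes 8-15  bounding box top, left, bottom, right (shorts)
#   bytes 16-17 number of coordinates n
#   bytes 18-63 unused here (floats/options/header2 offset zeroed)
#   bytes 64+   n shorts of x relative to left, then n shorts of y
#               relative to top
# Only integer-coordinate polygon/freehand outlines are represented; that is
# what the freehand selection tool produces once anchored to pixels.

#' Read an ImageJ .roi file (polygon/freehand subset)
#'
#' @param path Path to a `.roi` file.
#' @return Numeric n x 2 vertex matrix (x, y).
#' @export
read_imagej_roi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) stop_format(sprintf("'%s' is not an ImageJ ROI file", path))
  readBin(con, "integer", 1, size = 2, endian = "big")            # version
  type <- readBin(con, "integer", 1, size = 1)
  readBin(con, "integer", 1, size = 1)                            # unused
  if (!type %in% c(0L, 7L)) {
    stop_format(sprintf("unsupported ImageJ ROI type %d (only polygon/freehand)", type))
  }
  bbox <- readBin(con, "integer", 4, size = 2, endian = "big")    # top,left,bottom,right
  n <- readBin(con, "integer", 1, size = 2, endian = "big")
  if (n < 3) stop_format(sprintf("degenerate ROI in '%s': %d vertices", path, n))
  readBin(con, "raw", 64 - 18)                                    # skip to offset 64
  xs <- readBin(con, "integer", n, size = 2, endian = "big") + bbox[2]
  ys <- readBin(con, "integer", n, size = 2, endian = "big") + bbox[1]
  cbind(x = xs, y = ys)
}

#' Write an ImageJ .roi file (polygon subtype)
#'
#' Coordinates are rounded to integers, as ImageJ stores them.
#'
#' @param vertices Numeric n x 2 vertex matrix (x, y).
#' @param path Output path.
#' @param type ImageJ ROI type byte: 0 polygon (default), 7 freehand.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(vertices, path, type = 0L) {
  vertices <- round(as.matrix(vertices))
  if (nrow(vertices) < 3) stop_format("a polygon needs >= 3 vertices")
  xs <- as.integer(vertices[, 1]); ys <- as.integer(vertices[, 2])
  left <- min(xs); top <- min(ys)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, nchars = 4, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")
  writeBin(as.integer(type), con, size = 1)
  writeBin(0L, con, size = 1)
  writeBin(c(top, left, max(ys), max(xs)), con, size = 2, endian = "big")
  writeBin(length(xs), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)
  writeBin(xs - left, con, size = 2, endian = "big")
  writeBin(ys - top, con, size = 2, endian = "big")
  invisible(path)
}
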