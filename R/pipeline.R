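# Pipeline orchestration: quantify a frame/scene/cohort, and the
# simulate -> quantify -> report stages used by the command-line wrapper.

#' Quantify all lesions on a single analysis frame
#'
#' For every CNV / CR-burn ROI: rasterize the outline, build the background
#' annulus (twice-the-radius rule), sample six vessel-free background
#' patches, and compute area, ONH-normalized area, lesion and background
#' mean grey, net fluorescence and the area-corrected intensity score. A
#' lesion that cannot be measured (vessels cover it, or the annulus offers
#' too little vessel-free area) yields a row flagged in `qc_flags` rather
#' than an error.
#'
#' @param frame Numeric grey matrix (the analysis frame).
#' @param rois A [roi_set()] containing the lesion outlines, at least one
#'   ONH outline, and optionally vessel ROIs.
#' @param frame_time Timestamp of the frame (seconds), recorded in the
#'   output.
#' @param vessel_mask Optional explicit vessel mask (logical matrix); the
#'   union with any vessel-role ROIs is excluded from all intensity means.
#' @param annulus_scale Outer/inner border scale of the annulus (default 2).
#' @param patch_side Background patch side (pixels); `NULL` for the
#'   lesion-size default.
#' @param seed Seed for the background patch tie-breaks.
#' @return Tibble, one row per lesion: `lesion_id`, `role`, `frame_time_s`,
#'   `area_px`, `onh_mean_px`, `normalized_area`, `lesion_mean`,
#'   `background_mean`, `net_fluorescence`, `area_corrected_intensity`,
#'   `n_background_patches`, `clip_fraction`, `qc_flags`.
#' @export
quantify_frame <- function(frame, rois, frame_time = NA_real_,
                           vessel_mask = NULL, annulus_scale = 2,
                           patch_side = NULL, seed = 1L) {
  stopifnot(is.matrix(frame), inherits(rois, "roi_set"))
  shape <- dim(frame)

  onh_rois <- rois_by_role(rois, "ONH")
  if (!length(onh_rois)) stop_data("ROI set contains no ONH outline")
  onh_areas <- vapply(onh_rois, roi_area_px, 0, frame_shape = shape)

  vmask <- matrix(FALSE, shape[1], shape[2])
  for (vr in rois_by_role(rois, "vessel")) {
    vmask <- vmask | rasterize_roi(vr, shape)
  }
  if (!is.null(vessel_mask)) vmask <- vmask | vessel_mask

  lesions <- c(rois_by_role(rois, "CNV"), rois_by_role(rois, "CR_burn"))
  rows <- lapply(lesions, function(les) {
    base <- tibble(
      lesion_id = les$lesion_id, role = les$role, frame_time_s = frame_time,
      area_px = NA_integer_, onh_mean_px = mean(onh_areas),
      normalized_area = NA_real_, lesion_mean = NA_real_,
      background_mean = NA_real_, net_fluorescence = NA_real_,
      area_corrected_intensity = NA_real_, n_background_patches = 0L,
      clip_fraction = NA_real_, qc_flags = ""
    )
    tryCatch({
      lmask <- rasterize_roi(les, shape)
      base$area_px <- sum(lmask)
      base$normalized_area <- normalize_area(base$area_px, onh_areas)
      ann <- build_annulus(les, shape, scale = annulus_scale)
      base$clip_fraction <- ann$clip_fraction
      base$lesion_mean <- lesion_mean_grey(frame, lmask, vmask, les$lesion_id)
      bg <- sample_background(frame, ann, vmask, patch_side = patch_side,
                              seed = seed, lesion_id = les$lesion_id)
      base$background_mean <- bg$background_mean
      base$n_background_patches <- nrow(bg$patch_centers)
      base$net_fluorescence <- net_fluorescence(base$lesion_mean, base$background_mean)
      base$area_corrected_intensity <-
        area_corrected_intensity(base$net_fluorescence, base$normalized_area)
      base
    }, ffa_unquantifiable_error = function(e) {
      base$qc_flags <- sprintf("unquantifiable: %s", conditionMessage(e))
      base
    })
  })
  dplyr::bind_rows(rows)
}

#' Quantify one scene (sequence + ROIs) at the cohort analysis time
#'
#' Extracts the green channel if needed, selects the frame nearest
#' `target_time`, and runs [quantify_frame()].
#'
#' @param seq A [frame_sequence()] (RGB or grey).
#' @param rois A [roi_set()].
#' @param target_time Analysis time in seconds (default 10.2, the cohort
#'   peak of CNV fluorescence after intravenous injection).
#' @param ... Passed to [quantify_frame()].
#' @return The [quantify_frame()] tibble.
#' @export
quantify_scene <- function(seq, rois, target_time = 10.2, ...) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (n_channels(seq) == 3) seq <- extract_green(seq)
  idx <- select_analysis_frame(seq, target_time)
  quantify_frame(seq$frames[[idx]], rois, frame_time = seq$times[idx], ...)
}

#' Quantify every eye of a phantom cohort
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param ... Passed to [quantify_scene()].
#' @return Tibble of per-lesion metrics across all eyes.
#' @export
quantify_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dplyr::bind_rows(lapply(cohort$scenes, function(sc) {
    quantify_scene(sc$sequence, sc$rois, ...)
  }))
}

# ---- disk-level stages (used by the CLI wrapper) ---------------------------

#' Write a phantom cohort bundle to disk
#'
#' Lays out one directory per eye (`frames.tif`, `rois.json`, a vessel mask
#' PNG under `masks/`, and `meta.json` with timestamps and route), plus
#' `manifest.csv` and `truth.json` at the root -- exactly the formats the
#' quantification stage reads.
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (eye_id in names(cohort$scenes)) {
    sc <- cohort$scenes[[eye_id]]
    d <- file.path(out_dir, eye_id)
    dir.create(d, showWarnings = FALSE)
    write_frame_sequence(sc$sequence, file.path(d, "frames.tif"))
    polys <- Filter(function(r) r$geometry == "polygon", sc$rois$rois)
    masks <- Filter(function(r) r$geometry == "mask", sc$rois$rois)
    write_roi_set(roi_set(polys), file.path(d, "rois.json"), "json")
    if (length(masks)) {
      write_roi_set(roi_set(masks), file.path(d, "masks"), "mask",
                    frame_shape = frame_shape(sc$sequence))
    }
    jsonlite::write_json(
      list(times = sc$sequence$times, bit_depth = sc$sequence$bit_depth,
           route = sc$truth$route),
      file.path(d, "meta.json"), digits = NA)
  }
  write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(out_dir)
}

#' Simulate a phantom cohort from a JSON spec and write it to disk
#'
#' @param spec Path to a JSON file, or a list, with any of the fields of
#'   [generate_cohort()] (`n_per_group`, `effect`, `width`, `height`,
#'   `noise_sd`, `lesions_per_eye`, `seed`, ...).
#' @param out_dir Output directory.
#' @param seed Overrides the spec's seed when non-`NULL`.
#' @return The cohort bundle, invisibly.
#' @export
run_simulate <- function(spec = list(), out_dir, seed = NULL) {
  if (is.character(spec)) {
    if (!file.exists(spec)) stop_format(sprintf("no such spec file: '%s'", spec))
    spec <- jsonlite::fromJSON(spec, simplifyVector = TRUE)
  }
  if (!is.list(spec)) stop_format("cohort spec must be a JSON object")
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  allowed <- names(formals(generate_cohort))
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown)) {
    stop_format(sprintf("unknown cohort spec field(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.null(spec$lesions_per_eye)) {
    spec$lesions_per_eye <- do.call(seq, as.list(range(spec$lesions_per_eye)))
  }
  cohort <- do.call(generate_cohort, spec)
  write_cohort(cohort, out_dir)
  invisible(cohort)
}

read_eye_dir <- function(d) {
  tif <- file.path(d, "frames.tif")
  if (!file.exists(tif)) stop_format(sprintf("missing TIFF: '%s'", tif))
  meta <- jsonlite::fromJSON(file.path(d, "meta.json"))
  seq <- read_frame_sequence(tif, times = meta$times)
  rois <- read_roi_set(file.path(d, "rois.json"), "json")$rois
  mask_dir <- file.path(d, "masks")
  if (dir.exists(mask_dir)) {
    rois <- c(rois, read_roi_set(mask_dir, "mask")$rois)
  }
  list(sequence = seq, rois = roi_set(rois), route = meta$route %||% "IV")
}

#' Quantify an on-disk cohort bundle
#'
#' Reads every eye directory listed in `manifest.csv`, quantifies each at
#' the analysis time, and writes `lesions.csv`. A single unquantifiable
#' lesion is flagged, never fatal.
#'
#' @param input_dir Bundle directory as written by [run_simulate()] /
#'   [write_cohort()].
#' @param out_dir Where `lesions.csv` goes (default `input_dir`).
#' @param target_time Analysis time (seconds).
#' @param annulus_scale,patch_side,seed Passed to [quantify_frame()].
#' @return Tibble of per-lesion metrics joined to the manifest.
#' @export
run_quantify <- function(input_dir, out_dir = input_dir, target_time = 10.2,
                         annulus_scale = 2, patch_side = NULL, seed = 1L) {
  mf <- file.path(input_dir, "manifest.csv")
  if (!file.exists(mf)) stop_format(sprintf("missing manifest: '%s'", mf))
  manifest <- as_tibble(read.csv(mf))
  eyes <- unique(file.path(input_dir, paste0(manifest$animal_id, "_", manifest$eye)))
  metrics <- dplyr::bind_rows(lapply(eyes, function(d) {
    eye <- read_eye_dir(d)
    quantify_scene(eye$sequence, eye$rois, target_time = target_time,
                   annulus_scale = annulus_scale, patch_side = patch_side,
                   seed = seed)
  }))
  metrics <- dplyr::left_join(
    metrics, manifest[c("lesion_id", "animal_id", "eye", "group", "week", "route")],
    by = "lesion_id")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(metrics, file.path(out_dir, "lesions.csv"), row.names = FALSE)
  metrics
}

#' Summarize, test and render a report for quantified lesions
#'
#' @param metrics Tibble from [run_quantify()] or path to a `lesions.csv`.
#' @param out_dir Report output directory.
#' @param by_eye,exclude_weeks,variance See [summarize_lesions()] and
#'   [compare_groups()].
#' @return List with `summaries` and `tests`, invisibly.
#' @export
run_report <- function(metrics, out_dir, by_eye = FALSE, exclude_weeks = 1L,
                       variance = "pooled") {
  if (is.character(metrics)) {
    if (!file.exists(metrics)) stop_format(sprintf("no such metrics file: '%s'", metrics))
    metrics <- as_tibble(read.csv(metrics))
  }
  summaries <- summarize_lesions(metrics, by_eye = by_eye,
                                 exclude_weeks = exclude_weeks)
  tests <- compare_groups(metrics, by_eye = by_eye,
                          exclude_weeks = exclude_weeks, variance = variance)
  render_report(summaries, tests, out_dir)
  invisible(list(summaries = summaries, tests = tests))
}
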