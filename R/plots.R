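# ggplot2 figures: trace plots, group bar charts with SD whiskers and
# significance stars, QC overlays.

metric_label <- function(metric) {
  c(normalized_area = "Normalized lesion area (ONH units)",
    net_fluorescence = "Net fluorescence (grey levels)",
    area_corrected_intensity = "Area-corrected lesion intensity",
    flatmount_area_um2 = "Flatmount lesion area (µm²)")[metric] %||% metric
}

#' Bar chart of group summaries for one metric
#'
#' Mean with SD whiskers per group, faceted by week when several weeks are
#' present; significance stars are drawn over the tested group pairs.
#'
#' @param summaries Output of [summarize_lesions()].
#' @param tests Optional output of [compare_groups()].
#' @param metric Which metric to plot.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summaries, tests = NULL, metric) {
  dat <- dplyr::filter(as_tibble(summaries), .data$metric == !!metric)
  if (!nrow(dat)) stop_data(sprintf("no summaries for metric '%s'", metric))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean,
                                         fill = .data$group)) +
    ggplot2::geom_col(width = 0.65, colour = "grey20", show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~week, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric_label(metric)) +
    ggplot2::theme_bw()
  if (!is.null(tests) && nrow(tests)) {
    tst <- dplyr::filter(as_tibble(tests), .data$metric == !!metric,
                         .data$p_value < 0.05)
    if (nrow(tst)) {
      span <- max(dat$mean + dat$sd, 0) - min(dat$mean - dat$sd, 0)
      tst$label <- significance_stars(tst$p_value)
      tst$y <- max(dat$mean + dat$sd, 0) + 0.08 * span * seq_len(nrow(tst))
      p <- p + ggplot2::geom_text(
        data = tst,
        ggplot2::aes(x = 1.5, y = .data$y, label = .data$label),
        inherit.aes = FALSE, size = 5)
    }
  }
  p
}

#' @describeIn plot_group_summary Plot a time-intensity trace with its
#'   detected appearance and peak.
#' @param object,x An `ffa_trace`.
#' @param ... Unused.
#' @export
autoplot.ffa_trace <- function(object, ...) {
  pk <- detect_peak(object)
  app <- tryCatch(detect_appearance(object), error = function(e) NULL)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean_grey)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = pk$peak_time, linetype = "dashed") +
    ggplot2::labs(x = "Time post injection (s)", y = "Mean grey value",
                  title = attr(object, "lesion_id")) +
    ggplot2::theme_bw()
  if (!is.null(app) && app$defined) {
    p <- p + ggplot2::geom_vline(xintercept = app$appearance_time,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' @export
plot.ffa_trace <- function(x, ...) print(autoplot(x, ...))

#' @describeIn plot_group_summary Plot a fitted kinetics model over its trace.
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  p <- autoplot(object$trace)
  if (object$converged) {
    fitted <- tibble(time = object$trace$time,
                     mean_grey = predict(object))
    p <- p + ggplot2::geom_line(data = fitted, colour = "firebrick",
                                linewidth = 0.4)
  }
  p
}

#' QC overlay of a quantified lesion
#'
#' Renders the analysis frame with the lesion outline, annulus extent and
#' the six background patches, for visual review of what was measured.
#'
#' @param frame Grey matrix (the analysis frame).
#' @param annulus An [build_annulus()] result.
#' @param background A [sample_background()] result.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(frame, annulus, background, path) {
  maxv <- max(frame, 1)
  rgb <- array(frame / maxv, dim = c(nrow(frame), ncol(frame), 3))
  edge <- function(mask) mask & !(rbind(mask[-1, ], FALSE) &
                                    rbind(FALSE, mask[-nrow(mask), ]) &
                                    cbind(mask[, -1], FALSE) &
                                    cbind(FALSE, mask[, -ncol(mask)]))
  le <- edge(annulus$lesion_mask); ae <- edge(annulus$mask)
  rgb[, , 1][le] <- 1; rgb[, , 2][le] <- 0; rgb[, , 3][le] <- 0
  rgb[, , 2][ae] <- 1; rgb[, , 1][ae] <- 0; rgb[, , 3][ae] <- 0
  s <- background$patch_side
  off_lo <- -((s - 1L) %/% 2L); off_hi <- s %/% 2L
  for (i in seq_len(nrow(background$patch_centers))) {
    rows <- (background$patch_centers$y[i] + off_lo):(background$patch_centers$y[i] + off_hi) + 1L
    cols <- (background$patch_centers$x[i] + off_lo):(background$patch_centers$x[i] + off_hi) + 1L
    rgb[rows, cols, 3] <- 1
  }
  png::writePNG(rgb, path)
  invisible(path)
}
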