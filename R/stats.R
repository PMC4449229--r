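# Group statistics: mean +/- SD summaries per (group, week, metric) and
# two-tailed two-sample t-tests, reported the way the treatment comparison
# figures are laid out.

METRIC_COLS <- c("normalized_area", "net_fluorescence",
                 "area_corrected_intensity", "flatmount_area_um2")

#' Summarize per-lesion metrics by group and week
#'
#' Joins lesion metrics to the study manifest and produces one mean +/- SD
#' summary per (group, week, metric). Lesions flagged unquantifiable (any
#' non-empty `qc_flags`) are excluded, as are whole weeks named in
#' `exclude_weeks` -- by default week 1, where lesion borders are too
#' poorly defined to outline. Excluded counts are attached as attribute
#' `"excluded"`; included + excluded always equals the input count.
#'
#' @param metrics Tibble of per-lesion metrics (must contain `lesion_id`
#'   and at least one of `normalized_area`, `net_fluorescence`,
#'   `area_corrected_intensity`, `flatmount_area_um2`; an optional
#'   `qc_flags` column marks unquantifiable lesions).
#' @param manifest Tibble mapping `lesion_id` to `group` and `week` (and
#'   usually `animal_id`, `eye`, `route`). `NULL` if `metrics` already
#'   carries `group`/`week` columns.
#' @param by_eye Average lesions within an eye first, so the experimental
#'   unit becomes the eye rather than the lesion (default `FALSE`,
#'   lesion-level, matching the reported group sizes).
#' @param exclude_weeks Weeks dropped from analysis (default 1).
#' @return Tibble: `group`, `week`, `metric`, `n`, `mean`, `sd`.
#' @export
summarize_lesions <- function(metrics, manifest = NULL, by_eye = FALSE,
                              exclude_weeks = 1L) {
  metrics <- as_tibble(metrics)
  if (!is.null(manifest)) {
    manifest <- as_tibble(manifest)
    orphans <- setdiff(metrics$lesion_id, manifest$lesion_id)
    if (length(orphans)) {
      stop_data(sprintf("lesions missing from the manifest: %s",
                        paste(head(orphans, 5), collapse = ", ")))
    }
    keep <- setdiff(names(manifest), setdiff(names(metrics), "lesion_id"))
    metrics <- dplyr::inner_join(metrics, manifest[keep], by = "lesion_id")
  }
  if (!all(c("group", "week") %in% names(metrics))) {
    stop_data("metrics must carry `group` and `week` (directly or via the manifest)")
  }
  n_in <- nrow(metrics)
  flagged <- if ("qc_flags" %in% names(metrics)) {
    !is.na(metrics$qc_flags) & metrics$qc_flags != ""
  } else rep(FALSE, n_in)
  wk_excl <- metrics$week %in% exclude_weeks
  excluded <- list(qc_flagged = sum(flagged & !wk_excl),
                   week_excluded = sum(wk_excl), included = sum(!flagged & !wk_excl))
  stopifnot(excluded$qc_flagged + excluded$week_excluded + excluded$included == n_in)
  dat <- metrics[!flagged & !wk_excl, ]

  value_cols <- intersect(METRIC_COLS, names(dat))
  if (!length(value_cols)) stop_data("no metric columns found")
  long <- tidyr::pivot_longer(dat, dplyr::all_of(value_cols),
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  if (by_eye) {
    long <- long |>
      dplyr::group_by(.data$group, .data$week, .data$metric,
                      .data$animal_id, .data$eye) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  out <- long |>
    dplyr::group_by(.data$group, .data$week, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  attr(out, "excluded") <- excluded
  out
}

#' Two-tailed two-sample t-test
#'
#' Classical Student's t-test with pooled variance by default (Welch's
#' unpooled form selectable). When both samples are constant and equal the
#' statistic is defined as t = 0, p = 1.
#'
#' @param a,b Numeric samples, each of length >= 2, finite.
#' @param variance `"pooled"` (Student, default) or `"welch"`.
#' @param alpha Significance level used for the `significant` flag.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `significant`.
#' @export
ttest_two_tailed <- function(a, b, variance = c("pooled", "welch"), alpha = 0.05) {
  variance <- match.arg(variance)
  if (length(a) < 2 || length(b) < 2) stop_data("each sample needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop_data("samples must be finite")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    ht <- t.test(a, b, var.equal = variance == "pooled",
                 alternative = "two.sided")
    res <- list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
                p.value = ht$p.value)
  }
  tibble(t = res$statistic, df = res$parameter, p_value = res$p.value,
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b),
         significant = res$p.value < alpha)
}

#' Pairwise group comparisons of lesion metrics
#'
#' Runs [ttest_two_tailed()] for every metric, week and pair of groups with
#' at least two lesions per side. No multiple-testing correction is applied
#' by default, mirroring the original analysis; `p_adjust = "holm"` is
#' available.
#'
#' @inheritParams summarize_lesions
#' @param variance Passed to [ttest_two_tailed()].
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Tibble with one row per (metric, week, group pair).
#' @export
compare_groups <- function(metrics, manifest = NULL, by_eye = FALSE,
                           exclude_weeks = 1L,
                           variance = c("pooled", "welch"),
                           p_adjust = "none") {
  variance <- match.arg(variance)
  metrics <- as_tibble(metrics)
  if (!is.null(manifest)) {
    manifest <- as_tibble(manifest)
    keep <- setdiff(names(manifest), setdiff(names(metrics), "lesion_id"))
    metrics <- dplyr::inner_join(metrics, manifest[keep], by = "lesion_id")
  }
  flagged <- if ("qc_flags" %in% names(metrics)) {
    !is.na(metrics$qc_flags) & metrics$qc_flags != ""
  } else rep(FALSE, nrow(metrics))
  dat <- metrics[!flagged & !(metrics$week %in% exclude_weeks), ]
  value_cols <- intersect(METRIC_COLS, names(dat))
  long <- tidyr::pivot_longer(dat, dplyr::all_of(value_cols),
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  if (by_eye) {
    long <- long |>
      dplyr::group_by(.data$group, .data$week, .data$metric,
                      .data$animal_id, .data$eye) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  combos <- long |>
    dplyr::distinct(.data$metric, .data$week) |>
    dplyr::arrange(.data$metric, .data$week)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- dplyr::filter(long, .data$metric == combos$metric[i],
                         .data$week == combos$week[i])
    grps <- sort(unique(sub$group))
    if (length(grps) < 2) next
    prs <- utils::combn(grps, 2, simplify = FALSE)
    for (pr in prs) {
      va <- sub$value[sub$group == pr[1]]
      vb <- sub$value[sub$group == pr[2]]
      if (length(va) < 2 || length(vb) < 2) next
      tt <- ttest_two_tailed(va, vb, variance = variance)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(metric = combos$metric[i], week = combos$week[i],
               group_a = pr[1], group_b = pr[2]), tt)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) && p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
    out$significant <- out$p_value < 0.05
  }
  out
}

#' Significance stars for p-values
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Write the report bundle: summary tables, test tables and figures
#'
#' Emits `summaries.csv`, `tests.csv` and one bar chart per metric (mean
#' with SD whiskers per group and week, significance stars for tested
#' pairs).
#'
#' @param summaries Output of [summarize_lesions()].
#' @param tests Output of [compare_groups()] (may be empty).
#' @param out_dir Output directory (created if needed).
#' @param format Figure device, `"png"` or `"svg"`.
#' @return Invisible character vector of the files written.
#' @export
render_report <- function(summaries, tests = NULL, out_dir, format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  f_sum <- file.path(out_dir, "summaries.csv")
  write.csv(summaries, f_sum, row.names = FALSE)
  paths <- c(paths, f_sum)
  if (!is.null(tests) && nrow(tests)) {
    f_tst <- file.path(out_dir, "tests.csv")
    write.csv(tests, f_tst, row.names = FALSE)
    paths <- c(paths, f_tst)
  }
  for (mt in unique(summaries$metric)) {
    p <- plot_group_summary(summaries, tests, metric = mt)
    f <- file.path(out_dir, sprintf("%s.%s", mt, format))
    dev <- if (format == "png") grDevices::png else grDevices::svg
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 150, device = dev)
    paths <- c(paths, f)
  }
  invisible(paths)
}
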