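# Fluorescein kinetics: per-lesion time-intensity traces, appearance and
# peak detection, and empirical model fits for the two administration
# routes. Intravenous bolus passage is modelled with a gamma-variate,
# v(t) = A * ((t - t0)/theta)^alpha * exp(alpha * (1 - (t - t0)/theta)),
# which peaks at t0 + theta with value A; intraperitoneal uptake with a
# saturating logarithmic rise v(t) = A * log(1 + (t - t0)/tau). Both are
# empirical conveniences layered on the qualitative behaviour of the two
# routes, not perfusion models.

#' Gamma-variate bolus curve
#'
#' Parameterized so `A` is the peak value, reached at `t0 + theta`;
#' zero for `t <= t0`.
#'
#' @param t Time (seconds).
#' @param A Peak amplitude (grey levels, > 0).
#' @param t0 Bolus arrival time (seconds).
#' @param theta Time from arrival to peak (seconds, > 0).
#' @param alpha Shape exponent (> 0); larger is more symmetric.
#' @return Curve values at `t`.
#' @export
gamma_variate <- function(t, A, t0, theta, alpha = 2) {
  u <- (t - t0) / theta
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- A * u[pos]^alpha * exp(alpha * (1 - u[pos]))
  out
}

#' Saturating logarithmic rise (intraperitoneal uptake)
#'
#' Zero for `t <= t0`, then `A * log(1 + (t - t0)/tau)`: monotone
#' non-decreasing over any observation window, so the peak is censored at
#' the window end.
#'
#' @param t Time (seconds).
#' @param A Amplitude scale (grey levels, > 0).
#' @param t0 Appearance delay (seconds).
#' @param tau Rise time-scale (seconds, > 0).
#' @return Curve values at `t`.
#' @export
log_rise <- function(t, A, t0, tau) {
  u <- (t - t0) / tau
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- A * log1p(u[pos])
  out
}

new_trace <- function(times, values, lesion_id = NA_character_) {
  tr <- tibble(time = as.double(times), mean_grey = as.double(values))
  attr(tr, "lesion_id") <- lesion_id
  class(tr) <- c("ffa_trace", class(tr))
  tr
}

#' Extract a per-lesion time-intensity trace
#'
#' One vessel-excluded lesion mean grey value per frame, bound to the frame
#' timestamps.
#'
#' @param seq Single-channel [frame_sequence()].
#' @param lesion_mask Logical lesion pixel mask.
#' @param vessel_mask Optional logical vessel mask.
#' @param lesion_id Identifier carried on the trace.
#' @return A tibble of class `ffa_trace` with columns `time`, `mean_grey`.
#' @export
extract_trace <- function(seq, lesion_mask, vessel_mask = NULL,
                          lesion_id = NA_character_) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (n_channels(seq) != 1) stop_format("extract the green channel before tracing")
  vals <- vapply(seq$frames, lesion_mean_grey, 0,
                 lesion_mask = lesion_mask, vessel_mask = vessel_mask,
                 lesion_id = lesion_id)
  new_trace(seq$times, vals, lesion_id)
}

#' Detect fluorescein appearance time
#'
#' Appearance is the first time the trace exceeds
#' `baseline_mean + k * baseline_sd` and the following sample exceeds it
#' too (two-sample persistence guards against single-frame noise). The
#' baseline is estimated from the initial pre-arrival samples.
#'
#' @param trace An `ffa_trace`.
#' @param k Baseline SD multiplier (default 3).
#' @param n_baseline Number of initial frames treated as baseline; default
#'   `max(3, 5%` of the trace`)`.
#' @return One-row tibble: `appearance_time` (NA when no crossing),
#'   `defined`, `baseline_mean`, `baseline_sd`, `threshold`.
#' @export
detect_appearance <- function(trace, k = 3, n_baseline = NULL) {
  stopifnot(inherits(trace, "ffa_trace"))
  n <- nrow(trace)
  nb <- n_baseline %||% max(3L, as.integer(floor(0.05 * n)))
  if (n < nb + 2) stop_data(sprintf("trace too short (%d) for %d baseline frames", n, nb))
  base <- trace$mean_grey[seq_len(nb)]
  thr <- mean(base) + k * sd(base)
  above <- trace$mean_grey > thr
  idx <- which(above & c(above[-1], FALSE))
  idx <- idx[idx > nb]
  tibble(
    appearance_time = if (length(idx)) trace$time[idx[1]] else NA_real_,
    defined = length(idx) > 0,
    baseline_mean = mean(base), baseline_sd = sd(base), threshold = thr
  )
}

#' Detect the peak of a time-intensity trace
#'
#' The peak frame is the argmax of a moving-average-smoothed copy of the
#' trace; the smoothing only locates the peak, while the reported
#' `peak_value` is the raw trace value at that frame. A maximum on the
#' final frame is flagged censored -- on the intraperitoneal schedule the
#' intensity is still rising at the end of the 10-minute window, so peak
#' times there are right-censored rather than observed.
#'
#' @param trace An `ffa_trace`.
#' @param smooth_window Moving-average window in frames; default 5 when the
#'   sampling interval is below 0.2 s (video-rate capture), else 1.
#' @return One-row tibble: `peak_time`, `peak_value`, `censored`.
#' @export
detect_peak <- function(trace, smooth_window = NULL) {
  stopifnot(inherits(trace, "ffa_trace"))
  n <- nrow(trace)
  if (is.null(smooth_window)) {
    dt <- if (n > 1) median(diff(trace$time)) else Inf
    smooth_window <- if (dt < 0.2) 5L else 1L
  }
  if (n < smooth_window) stop_data("trace shorter than the smoothing window")
  sm <- moving_average(trace$mean_grey, smooth_window)
  i <- which.max(sm)
  tibble(peak_time = trace$time[i], peak_value = trace$mean_grey[i],
         censored = i == n)
}

#' Fit an administration-route kinetics model to a trace
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the
#' gamma-variate (route `"IV"`) or logarithmic-rise (route `"IP"`) form,
#' plus a constant baseline offset. Starting values come from
#' [detect_appearance()] and [detect_peak()]. A trace with no defined
#' appearance, or a fit that fails to converge, yields an object with
#' `converged = FALSE` (the trace is still usable via [detect_peak()]).
#'
#' @param trace An `ffa_trace`.
#' @param route `"IV"` or `"IP"`.
#' @return Object of class `kinetics_fit`; see [tidy.kinetics_fit()] and
#'   [glance.kinetics_fit()].
#' @export
fit_kinetics <- function(trace, route = c("IV", "IP")) {
  stopifnot(inherits(trace, "ffa_trace"))
  route <- match.arg(route)
  t <- trace$time; y <- trace$mean_grey
  app <- tryCatch(detect_appearance(trace), error = function(e) NULL)
  pk <- detect_peak(trace)

  failed <- function(reason) {
    structure(list(route = route, converged = FALSE, reason = reason,
                   params = NULL, rmse = NA_real_, peak_time = NA_real_,
                   censored = pk$censored, trace = trace, fit = NULL),
              class = "kinetics_fit")
  }
  if (is.null(app) || !app$defined) return(failed("no defined appearance"))
  if (route == "IP" && sum(t > app$appearance_time) < 10) {
    return(failed("fewer than 10 post-appearance points"))
  }

  b0_start <- app$baseline_mean
  fit <- tryCatch({
    if (route == "IV") {
      A0 <- max(pk$peak_value - b0_start, 1e-3)
      t00 <- max(min(app$appearance_time, pk$peak_time - 0.1), min(t))
      th0 <- max(pk$peak_time - t00, 0.5)
      minpack.lm::nlsLM(
        y ~ b0 + gamma_variate(t, A, t0, theta, alpha),
        start = list(b0 = b0_start, A = A0, t0 = t00, theta = th0, alpha = 2),
        lower = c(b0 = -Inf, A = 1e-6, t0 = min(t) - 1, theta = 1e-2, alpha = 0.1),
        upper = c(b0 = Inf, A = Inf, t0 = max(t), theta = max(t) - min(t), alpha = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      t00 <- app$appearance_time
      tau0 <- max((max(t) - t00) / 10, 1)
      A0 <- max((max(y) - b0_start) / log1p((max(t) - t00) / tau0), 1e-3)
      minpack.lm::nlsLM(
        y ~ b0 + log_rise(t, A, t0, tau),
        start = list(b0 = b0_start, A = A0, t0 = t00, tau = tau0),
        lower = c(b0 = -Inf, A = 1e-6, t0 = min(t) - 1, tau = 1e-2),
        upper = c(b0 = Inf, A = Inf, t0 = max(t), tau = 10 * (max(t) - min(t))),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed("nonlinear least squares did not converge"))

  p <- as.list(coef(fit))
  rmse <- sqrt(mean(residuals(fit)^2))
  peak_time <- if (route == "IV") p$t0 + p$theta else NA_real_
  structure(
    list(route = route, converged = TRUE, reason = NULL, params = p,
         rmse = rmse, peak_time = peak_time, censored = pk$censored,
         trace = trace, fit = fit),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<kinetics_fit %s: FAILED (%s)>\n", x$route, x$reason))
  } else {
    cat(sprintf("<kinetics_fit %s: %s, rmse=%.3f%s>\n", x$route,
                paste(sprintf("%s=%.3g", names(x$params), unlist(x$params)),
                      collapse = " "),
                x$rmse,
                if (is.na(x$peak_time)) "" else sprintf(", peak=%.2f s", x$peak_time)))
  }
  invisible(x)
}

#' @export
predict.kinetics_fit <- function(object, times = NULL, ...) {
  if (!object$converged) stop_data("cannot predict from a failed fit")
  t <- times %||% object$trace$time
  p <- object$params
  if (object$route == "IV") {
    p$b0 + gamma_variate(t, p$A, p$t0, p$theta, p$alpha)
  } else {
    p$b0 + log_rise(t, p$A, p$t0, p$tau)
  }
}

#' Select the analysis frame nearest a target time
#'
#' Intensity quantification uses a single cohort-level analysis time (10.2
#' seconds post intravenous injection, the empirical peak of CNV
#' fluorescence) so that all animals are measured at the same point of the
#' bolus passage. Ties go to the earlier frame; a target beyond the last
#' frame clamps with a warning.
#'
#' @param seq A [frame_sequence()].
#' @param target_time Target time in seconds (default 10.2).
#' @return Integer frame index (1-based).
#' @export
select_analysis_frame <- function(seq, target_time = 10.2) {
  stopifnot(inherits(seq, "frame_sequence"), length(seq) >= 1)
  if (target_time > max(seq$times)) {
    warn(sprintf("target time %.2f s is beyond the last frame (%.2f s); using the last frame",
                 target_time, max(seq$times)), class = "ffa_out_of_range")
  }
  which.min(abs(seq$times - target_time))[1]
}
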