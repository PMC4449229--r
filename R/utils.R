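# Internal helpers: condition constructors and small numeric utilities.

ffa_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ffa_error"), ...)
}

stop_format <- function(message, ...) ffa_abort(message, "ffa_format_error", ...)
stop_schedule <- function(message, ...) ffa_abort(message, "ffa_schedule_error", ...)
stop_data <- function(message, ...) ffa_abort(message, "ffa_data_error", ...)
stop_unquantifiable <- function(message, lesion_id = NULL, ...) {
  ffa_abort(message, "ffa_unquantifiable_error", lesion_id = lesion_id, ...)
}

#' Summed-area table lookup of box sums over a matrix
#'
#' Computes, for every position of a h x w matrix, the sum of values in the
#' axis-aligned box of the given half-widths centred there (boxes extending
#' past the matrix count the outside as 0). Used to test whether a square
#' background patch fits entirely inside an allowed region.
#'
#' @noRd
box_sums <- function(m, lo, hi) {
  # integral image with a zero top row / left column
  sat <- rbind(0, cbind(0, apply(apply(m, 2, cumsum), 1, cumsum) |> t()))
  h <- nrow(m); w <- ncol(m)
  r1 <- pmax(1L, seq_len(h) + lo); r2 <- pmin(h, seq_len(h) + hi)
  c1 <- pmax(1L, seq_len(w) + lo); c2 <- pmin(w, seq_len(w) + hi)
  out <- matrix(0, h, w)
  for (j in seq_len(w)) {
    out[, j] <- sat[r2 + 1L, c2[j] + 1L] - sat[r1, c2[j] + 1L] -
      sat[r2 + 1L, c1[j]] + sat[r1, c1[j]]
  }
  out
}

# circular (mod 360) absolute angular distance in degrees
ang_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# centred moving average that shrinks the window at the edges
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(x)
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo); hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
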