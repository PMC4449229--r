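# broom-style methods for fitted kinetics models.

#' Tidy a kinetics fit
#'
#' One row per fitted parameter.
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.kinetics_fit <- function(x, ...) {
  if (!x$converged) return(tibble(term = character(0), estimate = double(0)))
  tibble(term = names(x$params), estimate = unlist(x$params, use.names = FALSE))
}

#' Glance at a kinetics fit
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return One-row tibble: `route`, `converged`, `rmse`, `peak_time`,
#'   `censored`, `n`.
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(route = x$route, converged = x$converged, rmse = x$rmse,
         peak_time = x$peak_time, censored = x$censored,
         n = nrow(x$trace))
}
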