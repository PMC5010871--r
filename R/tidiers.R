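# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a single-model fit
#'
#' @param x A `kin_fit` from [fit_series()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`, `init`.
#' @export
tidy.kin_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = as.numeric(x$params),
    init = as.numeric(x$init[names(x$params)])
  )
}

#' One-row fit summary
#'
#' @param x A `kin_fit` from [fit_series()].
#' @param ... Unused.
#' @return One-row tibble: `model`, `sse`, `r_squared`, `runs_p`,
#'   `iterations`, `converged_by`, `degenerate`.
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, sse = x$sse, r_squared = x$r_squared,
    runs_p = x$runs_p, iterations = as.integer(x$iterations),
    converged_by = x$converged_by, degenerate = x$degenerate
  )
}

#' Data with fitted values and residuals
#'
#' @param x A `kin_fit` from [fit_series()].
#' @param ... Unused.
#' @return Tibble: `cycle`, `signal`, `.fitted`, `.resid`.
#' @export
augment.kin_fit <- function(x, ...) {
  tibble::tibble(
    cycle = x$cycles, signal = x$signals,
    .fitted = x$fitted, .resid = x$signals - x$fitted
  )
}

#' @rdname run_pipeline
#' @param x A `kin_pipeline`.
#' @param ... Unused.
#' @export
tidy.kin_pipeline <- function(x, ...) x$fits

#' @rdname run_pipeline
#' @export
glance.kin_pipeline <- function(x, ...) x$summary
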