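# Kinetic models for peptide-array progress curves.
#
# Signals are background-subtracted fluorescence (may be negative); the
# independent variable is the instrument's reaction cycle number, never
# wall-clock time.

#' Model identifiers
#'
#' The three candidate progress-curve models:
#' \describe{
#'   \item{`eq1`}{simple negative exponential,
#'     `y = y0 + ymax * (1 - exp(-k * c))`; parameters `y0, ymax, k`.}
#'   \item{`eq2`}{background-corrected negative exponential,
#'     `y = y0 + ymax * (1 - exp(-k * (c - c0)))`; parameters
#'     `y0, ymax, k, c0`.}
#'   \item{`eq3`}{background-corrected rational hyperbolic,
#'     `y = ymax * vi * (c - c0) / (ymax + vi * (c - c0))`; parameters
#'     `ymax, vi, c0`. Linear accumulation at initial rate `vi` saturating
#'     at capacity `ymax`.}
#' }
#' @format Character vector of length 3.
#' @export
kin_models <- c("eq1", "eq2", "eq3")

# Canonical parameter order per model; this order fixes the optimizer's
# coordinate sweep order.
kin_param_names <- list(
  eq1 = c("y0", "ymax", "k"),
  eq2 = c("y0", "ymax", "k", "c0"),
  eq3 = c("ymax", "vi", "c0")
)

# Union of parameter columns used in tidy fit tables.
kin_all_params <- c("y0", "ymax", "k", "c0", "vi")

#' Describe a kinetic model
#'
#' Returns the model specification: identifier, ordered parameter names and
#' parameter count. The parameter order determines the coordinate-descent
#' sweep order in [fit_series()].
#'
#' @param model One of `"eq1"`, `"eq2"`, `"eq3"` (see [kin_models]).
#' @return An object of class `kin_model`: a list with `model_id`,
#'   `param_names`, `n_params` and a human-readable `label`.
#' @examples
#' kinetic_model("eq3")
#' @export
kinetic_model <- function(model = kin_models) {
  model <- match.arg(model)
  label <- switch(model,
    eq1 = "negative exponential",
    eq2 = "background-corrected negative exponential",
    eq3 = "background-corrected rational hyperbolic"
  )
  structure(
    list(
      model_id = model,
      param_names = kin_param_names[[model]],
      n_params = length(kin_param_names[[model]]),
      label = label
    ),
    class = "kin_model"
  )
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model> ", x$model_id, ": ", x$label, "\n", sep = "")
  cat("  parameters: ", paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_kin_model <- function(model) {
  if (inherits(model, "kin_model")) model else kinetic_model(model)
}

check_params <- function(spec, params) {
  missing <- setdiff(spec$param_names, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s) for ", spec$model_id, ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  p <- as.numeric(params[spec$param_names])
  if (!all(is.finite(p))) {
    stop("parameters must be finite", call. = FALSE)
  }
  names(p) <- spec$param_names
  p
}

#' Evaluate a kinetic model
#'
#' Computes the model signal at the given cycle numbers. Values at cycles
#' below `c0` are evaluated exactly as written (no clamping); callers decide
#' any masking.
#'
#' @param model Model id or a [kinetic_model()] object.
#' @param params Named numeric vector with the model's parameters.
#' @param cycles Numeric vector of cycle numbers.
#' @return Numeric vector of model signals, same length as `cycles`.
#' @examples
#' eval_kinetic("eq3", c(ymax = 100, vi = 2, c0 = 0), cycles = c(0, 50))
#' @export
eval_kinetic <- function(model, params, cycles) {
  spec <- as_kin_model(model)
  p <- check_params(spec, params)
  switch(spec$model_id,
    eq1 = p[["y0"]] + p[["ymax"]] * (1 - exp(-p[["k"]] * cycles)),
    eq2 = p[["y0"]] + p[["ymax"]] * (1 - exp(-p[["k"]] * (cycles - p[["c0"]]))),
    eq3 = {
      num <- p[["ymax"]] * p[["vi"]] * (cycles - p[["c0"]])
      den <- p[["ymax"]] + p[["vi"]] * (cycles - p[["c0"]])
      if (any(den == 0)) {
        stop("degenerate parameters: hyperbolic denominator vanishes at a ",
          "requested cycle",
          call. = FALSE
        )
      }
      num / den
    }
  )
}

#' Asymptotic signal of a kinetic model
#'
#' The limit of the model signal as the cycle number grows without bound:
#' `y0 + ymax` for the exponential models, `ymax` for the hyperbolic one.
#' The asymptote is only defined for a positive rate parameter (`k` or `vi`);
#' otherwise `NA` is returned with a warning.
#'
#' @inheritParams eval_kinetic
#' @return A single numeric value, or `NA` when undefined.
#' @examples
#' model_limit("eq2", c(y0 = 5, ymax = 100, k = 0.1, c0 = 0))
#' @export
model_limit <- function(model, params) {
  spec <- as_kin_model(model)
  p <- check_params(spec, params)
  rate <- if (spec$model_id == "eq3") p[["vi"]] else p[["k"]]
  if (rate <= 0) {
    warning("asymptote undefined for non-positive rate parameter",
      call. = FALSE
    )
    return(NA_real_)
  }
  if (spec$model_id == "eq3") p[["ymax"]] else p[["y0"]] + p[["ymax"]]
}

#' Early-reaction slope from the background-corrected exponential
#'
#' The derivative of the `eq2` model evaluated at a fixed cycle,
#' `v_ini = ymax * k * exp(-k * (c_eval - c0))`. This is the early-slope
#' statistic conventionally reported from kinomic time series; the default
#' evaluation cycle is 35.
#'
#' @param params Named numeric vector with `eq2` parameters
#'   (`y0` is not needed and ignored if absent).
#' @param c_eval Cycle at which the slope is evaluated (default 35).
#' @return A single numeric rate (signal units per cycle).
#' @examples
#' v_ini(c(ymax = 100, k = 0.1, c0 = 35))
#' @export
v_ini <- function(params, c_eval = 35) {
  needed <- c("ymax", "k", "c0")
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    stop("v_ini needs eq2 parameters: missing ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  p <- as.numeric(params[needed])
  if (!all(is.finite(p))) stop("parameters must be finite", call. = FALSE)
  p[1] * p[2] * exp(-p[2] * (c_eval - p[3]))
}

#' Reciprocal form of the rational hyperbolic model
#'
#' Evaluates `y = ((vi * (c - c0))^-1 + ymax^-1)^-1`, the harmonic-sum form
#' from which the hyperbolic model is derived (linear accumulation at rate
#' `vi` limited by capacity `ymax`). Exists to verify the derivation
#' identity against [eval_kinetic()]; requires `vi * (c - c0) > 0` and
#' `ymax > 0`.
#'
#' @param params Named numeric vector with `ymax`, `vi`, `c0`.
#' @param cycles Numeric vector of cycle numbers.
#' @return Numeric vector of model signals.
#' @export
eq3_reciprocal <- function(params, cycles) {
  spec <- kinetic_model("eq3")
  p <- check_params(spec, params)
  lin <- p[["vi"]] * (cycles - p[["c0"]])
  if (any(lin <= 0) || p[["ymax"]] <= 0) {
    stop("reciprocal form undefined: needs vi * (c - c0) > 0 and ymax > 0",
      call. = FALSE
    )
  }
  1 / (1 / lin + 1 / p[["ymax"]])
}

#' Algebraic starting values for a model fit
#'
#' Deterministic, seedless initial-parameter rules used before the
#' coordinate-descent fit:
#' \itemize{
#'   \item `c0` starts at the first cycle, `y0` at the first signal
#'     (exponential models);
#'   \item `ymax` starts at 1.5 x the observed signal range, floored at a
#'     small positive constant;
#'   \item `vi` starts at the slope of the first consecutive point pair with
#'     a positive signal change, floored;
#'   \item `k` is solved algebraically from the mid-series point given the
#'     other starting values, floored.
#' }
#' Flat (all-equal) signals carry no kinetic information; the floors are
#' returned and the result is flagged degenerate.
#'
#' @inheritParams eval_kinetic
#' @param cycles Strictly increasing numeric vector of cycle numbers.
#' @param signals Numeric vector of background-subtracted signals, same
#'   length as `cycles`.
#' @param floor Small positive constant bounding rate and capacity starts
#'   away from zero.
#' @return A list with `params` (named numeric vector in the model's sweep
#'   order) and `degenerate` (logical).
#' @examples
#' cyc <- seq(5, 65, by = 5)
#' sig <- eval_kinetic("eq3", c(ymax = 100, vi = 2, c0 = 0), cyc)
#' initial_params("eq3", cyc, sig)
#' @export
initial_params <- function(model, cycles, signals, floor = 1e-3) {
  spec <- as_kin_model(model)
  check_series(cycles, signals, min_len = spec$n_params + 1)

  degenerate <- all(signals == signals[1])
  rng <- max(signals) - min(signals)
  ymax0 <- max(1.5 * rng, floor)
  c0 <- cycles[1]
  y0 <- signals[1]

  # first consecutive pair with a positive signal change
  dsig <- diff(signals)
  idx <- which(dsig > 0)
  vi0 <- if (length(idx) > 0) {
    i <- idx[1]
    max(dsig[i] / (cycles[i + 1] - cycles[i]), floor)
  } else {
    floor
  }

  # k solved from the mid-series point given y0, ymax0 (and c0 for eq2)
  mid <- ceiling(length(cycles) / 2)
  solve_k <- function(offset) {
    frac <- (signals[mid] - y0) / ymax0
    dc <- cycles[mid] - offset
    if (frac > 0 && frac < 1 && dc > 0) {
      max(-log(1 - frac) / dc, floor)
    } else {
      floor
    }
  }

  params <- switch(spec$model_id,
    eq1 = c(y0 = y0, ymax = ymax0, k = solve_k(0)),
    eq2 = c(y0 = y0, ymax = ymax0, k = solve_k(c0), c0 = c0),
    eq3 = c(ymax = ymax0, vi = vi0, c0 = c0)
  )
  list(params = params, degenerate = degenerate)
}

check_series <- function(cycles, signals, min_len = 2) {
  if (length(cycles) != length(signals)) {
    stop("cycles and signals must have equal length", call. = FALSE)
  }
  if (any(!is.finite(cycles))) stop("cycles must be finite", call. = FALSE)
  if (any(diff(cycles) <= 0)) {
    stop("cycles must be strictly increasing", call. = FALSE)
  }
  if (length(cycles) < min_len) {
    stop("series too short: need at least ", min_len, " points",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Relative gain in residual degrees of freedom
#'
#' Percent increase in residual degrees of freedom when moving from a model
#' with `p_from` parameters to one with `p_to` parameters at a fixed number
#' of points per fit: `100 * ((n - p_to) - (n - p_from)) / (n - p_from)`.
#' With the platform's 13 points per curve, dropping from 4 to 3 parameters
#' gains about 11%.
#'
#' @param n_points Points per fitted curve (default 13).
#' @param p_from,p_to Parameter counts of the two models (defaults 4 and 3).
#' @return Percent gain (single numeric).
#' @examples
#' residual_df_gain()
#' @export
residual_df_gain <- function(n_points = 13, p_from = 4, p_to = 3) {
  df_from <- n_points - p_from
  df_to <- n_points - p_to
  100 * (df_to - df_from) / df_from
}
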