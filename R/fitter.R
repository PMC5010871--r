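# Coordinate-wise adaptive-step least-squares fitting.

#' Optimizer settings
#'
#' Control object for the coordinate-descent least-squares search. Each
#' parameter keeps its own signed step; a proposal `p_j + s_j` is accepted
#' only on a strict SSE decrease, after which the step grows by
#' `step_growth`; on rejection the parameter is restored and the step is
#' multiplied by `step_reversal` (direction reverses, magnitude halves).
#' One iteration is one full sweep over the parameters in the model's
#' declared order. The search stops when the percent change of SSE across a
#' sweep falls below `min_sse_percent_change`, or at `max_iterations`. A
#' sweep in which no proposal is accepted only reverses and halves the
#' steps and does not trigger the progress-based stop; a sweep starting at
#' SSE exactly 0 (perfect fit) terminates immediately.
#'
#' @param max_iterations Maximum number of full parameter sweeps.
#' @param initial_step_fraction Initial step as a signed fraction of each
#'   starting parameter value.
#' @param min_sse_percent_change Termination threshold on
#'   `100 * (SSE_prev - SSE_cur) / SSE_prev` across one sweep, in percent.
#' @param step_growth Step multiplier after an accepted proposal.
#' @param step_reversal Step multiplier after a rejected proposal.
#' @param zero_param_step Absolute initial step for parameters starting at
#'   exactly 0 (a fractional step would freeze them).
#' @return An object of class `kin_control` (a validated list).
#' @examples
#' fit_control(max_iterations = 500)
#' @export
fit_control <- function(max_iterations = 1000,
                        initial_step_fraction = 1 / 100,
                        min_sse_percent_change = 6e-5,
                        step_growth = 1.2,
                        step_reversal = -0.5,
                        zero_param_step = 0.01) {
  stopifnot(
    max_iterations >= 1,
    initial_step_fraction > 0,
    min_sse_percent_change > 0,
    zero_param_step > 0
  )
  structure(
    list(
      max_iterations = as.integer(max_iterations),
      initial_step_fraction = initial_step_fraction,
      min_sse_percent_change = min_sse_percent_change,
      step_growth = step_growth,
      step_reversal = step_reversal,
      zero_param_step = zero_param_step
    ),
    class = "kin_control"
  )
}

#' Residual sum of squares for a kinetic model
#'
#' @inheritParams initial_params
#' @param params Named numeric parameter vector.
#' @return `sum((eval_kinetic(model, params, cycles) - signals)^2)`.
#' @export
sse_kinetic <- function(model, params, cycles, signals) {
  check_series(cycles, signals, min_len = 1)
  sum((eval_kinetic(model, params, cycles) - signals)^2)
}

#' Generic coordinate-descent minimizer
#'
#' Minimizes an arbitrary scalar objective with the same adaptive-step
#' coordinate search used for the built-in models. Proposals with a
#' non-finite objective are rejected, which keeps the search inside the
#' feasible region without explicit bounds. Deterministic: there is no
#' randomness in the algorithm.
#'
#' @param objective Function of a numeric parameter vector returning a
#'   scalar (e.g. an SSE). Must be finite at `init`.
#' @param init Numeric starting vector.
#' @param control A [fit_control()] object.
#' @return List with `par`, `sse` (final objective), `iterations` (sweeps
#'   used) and `converged_by` (`"SSE_CHANGE"` or `"MAX_ITER"`).
#' @examples
#' obj <- function(p) (p[1] - 3)^2 + (p[2] + 1)^2
#' coord_descent(obj, c(0.5, 0.5))$par
#' @export
coord_descent <- function(objective, init, control = fit_control()) {
  p <- as.numeric(init)
  m <- length(p)
  s <- ifelse(p == 0, control$zero_param_step, p * control$initial_step_fraction)
  sse_cur <- objective(p)
  if (!is.finite(sse_cur)) {
    stop("invalid start: objective not finite at the initial parameters",
      call. = FALSE
    )
  }
  sse_prev_sweep <- sse_cur
  iters <- 0L
  converged_by <- "MAX_ITER"
  for (it in seq_len(control$max_iterations)) {
    iters <- it
    for (j in seq_len(m)) {
      prop <- p
      prop[j] <- p[j] + s[j]
      sse_new <- objective(prop)
      if (is.finite(sse_new) && sse_new < sse_cur) {
        p <- prop
        sse_cur <- sse_new
        s[j] <- s[j] * control$step_growth
      } else {
        s[j] <- s[j] * control$step_reversal
      }
    }
    if (sse_prev_sweep == 0) {
      converged_by <- "SSE_CHANGE"
      break
    }
    # an all-reject sweep (pct == 0) only reverses and halves the steps; it
    # must not trigger the progress-based stop
    pct <- 100 * (sse_prev_sweep - sse_cur) / sse_prev_sweep
    if (pct > 0 && pct < control$min_sse_percent_change) {
      converged_by <- "SSE_CHANGE"
      break
    }
    sse_prev_sweep <- sse_cur
  }
  list(
    par = stats::setNames(p, names(init)), sse = sse_cur,
    iterations = iters, converged_by = converged_by
  )
}

#' Fit one kinetic model to one peptide series
#'
#' Runs the coordinate-descent least-squares search from algebraic starting
#' values ([initial_params()]) and attaches goodness-of-fit measures:
#' R-squared and the one-sided Wald-Wolfowitz runs-test p-value on residual
#' signs ([runs_test()]).
#'
#' @inheritParams initial_params
#' @param init Optional named starting vector; computed by
#'   [initial_params()] when `NULL`.
#' @param control A [fit_control()] object.
#' @param engine `"cpp"` (compiled, default) or `"r"` (generic
#'   [coord_descent()] on [sse_kinetic()]); both implement the identical
#'   algorithm.
#' @return An object of class `kin_fit`: a list with the model id, fitted
#'   `params`, `sse`, `r_squared`, `runs_p`, `iterations`, `converged_by`,
#'   `degenerate`, and the data with `fitted` values. Supports
#'   [generics::tidy()], [generics::glance()], [generics::augment()] and
#'   [ggplot2::autoplot()].
#' @examples
#' cyc <- seq(5, 65, by = 5)
#' sig <- eval_kinetic("eq3", c(ymax = 300, vi = 8, c0 = 2), cyc)
#' fit_series(cyc, sig, "eq3")
#' @export
fit_series <- function(cycles, signals, model, init = NULL,
                       control = fit_control(), engine = c("cpp", "r")) {
  spec <- as_kin_model(model)
  engine <- match.arg(engine)
  check_series(cycles, signals, min_len = spec$n_params + 1)

  degenerate <- FALSE
  if (is.null(init)) {
    ip <- initial_params(spec, cycles, signals)
    init <- ip$params
    degenerate <- ip$degenerate
  } else {
    init <- check_params(spec, init)
  }

  res <- if (engine == "cpp") {
    coord_fit_cpp(
      match(spec$model_id, kin_models), cycles, signals, init,
      control$max_iterations, control$initial_step_fraction,
      control$min_sse_percent_change, control$step_growth,
      control$step_reversal, control$zero_param_step
    )
  } else {
    coord_descent(
      function(p) {
        sum((eval_model_cpp(
          match(spec$model_id, kin_models), p, cycles
        ) - signals)^2)
      },
      init, control
    )
  }

  params <- stats::setNames(as.numeric(res$par), spec$param_names)
  fitted <- as.vector(eval_model_cpp(
    match(spec$model_id, kin_models), params, cycles
  ))
  resid <- signals - fitted
  sstot <- sum((signals - mean(signals))^2)
  r2 <- if (sstot > 0) 1 - res$sse / sstot else NA_real_
  runs_p <- suppressWarnings(runs_test(resid))
  degenerate <- degenerate || !all(is.finite(params)) || !is.finite(res$sse)

  structure(
    list(
      model = spec$model_id,
      params = params,
      init = init,
      sse = res$sse,
      r_squared = r2,
      runs_p = as.numeric(runs_p),
      iterations = res$iterations,
      converged_by = res$converged_by,
      degenerate = degenerate,
      cycles = cycles,
      signals = signals,
      fitted = fitted
    ),
    class = "kin_fit"
  )
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("<kin_fit> model ", x$model,
    if (x$degenerate) " (degenerate)" else "", "\n",
    sep = ""
  )
  print(round(x$params, 6))
  cat(
    "  SSE ", format(x$sse, digits = 6),
    " | R^2 ", format(x$r_squared, digits = 4),
    " | runs p ", format(x$runs_p, digits = 4),
    " | ", x$iterations, " sweeps (", x$converged_by, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Fit all three models to one peptide series
#'
#' @inheritParams fit_series
#' @param models Subset of [kin_models] to fit.
#' @return Named list of `kin_fit` objects. A model whose parameter count
#'   exceeds `length(cycles) - 1` is skipped (absent from the list) with a
#'   message; a degenerate fit is returned with `degenerate = TRUE`, never
#'   an error.
#' @export
fit_all_models <- function(cycles, signals, models = kin_models,
                           control = fit_control()) {
  models <- match.arg(models, kin_models, several.ok = TRUE)
  out <- list()
  for (m in models) {
    spec <- kinetic_model(m)
    if (length(cycles) < spec$n_params + 1) {
      message(
        "skipping ", m, ": series has ", length(cycles),
        " points, needs at least ", spec$n_params + 1
      )
      next
    }
    out[[m]] <- tryCatch(
      fit_series(cycles, signals, m, control = control),
      error = function(e) {
        message("fit failed for ", m, ": ", conditionMessage(e))
        NULL
      }
    )
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Fit kinetic models across a whole dataset
#'
#' Data-frame-first fitting surface: takes a long table of per-peptide time
#' series and returns one tidy row per (sample, peptide, model) fit.
#' Individual peptide failures are recorded in the `note` column and never
#' abort the run.
#'
#' @param data Data frame with columns `peptide_id`, `cycle`, `signal` and
#'   optionally `sample_id` (and `replicate_set`, carried through).
#' @param models Subset of [kin_models] to fit.
#' @param control A [fit_control()] object.
#' @return A tibble with columns `sample_id`, `peptide_id`, `model`, the
#'   union of model parameters (`y0`, `ymax`, `k`, `c0`, `vi`; `NA` where a
#'   parameter does not belong to the model), `sse`, `r_squared`, `runs_p`,
#'   `iterations`, `converged_by`, `degenerate`, `note`.
#' @examples
#' chip <- simulate_chip(chip_sim_config(n_peptides = 3, seed = 7))
#' fit_kinetics(chip$data, models = "eq3")
#' @export
fit_kinetics <- function(data, models = kin_models, control = fit_control()) {
  models <- match.arg(models, kin_models, several.ok = TRUE)
  data <- as_kin_long(data)
  if (nrow(data) == 0) {
    return(empty_fit_tbl())
  }
  keys <- dplyr::distinct(data, .data$sample_id, .data$peptide_id)
  groups <- split(
    data,
    list(data$sample_id, data$peptide_id),
    drop = TRUE, sep = "\r"
  )
  rows <- purrr::map(groups, function(g) {
    g <- dplyr::arrange(g, .data$cycle)
    ok <- is.finite(g$signal)
    purrr::map(models, function(m) {
      fit_row(
        g$sample_id[1], g$peptide_id[1], m,
        g$cycle[ok], g$signal[ok], control
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out <- dplyr::arrange(
    out,
    .data$sample_id, .data$peptide_id,
    match(.data$model, kin_models)
  )
  # conservation: one row per requested (sample, peptide, model)
  stopifnot(nrow(out) == nrow(keys) * length(models))
  out
}

# returns a plain named list (one row); bound into a tibble by the caller
fit_row <- function(sample_id, peptide_id, model, cycles, signals, control) {
  spec <- kinetic_model(model)
  base <- list(
    sample_id = sample_id, peptide_id = peptide_id, model = model,
    y0 = NA_real_, ymax = NA_real_, k = NA_real_, c0 = NA_real_,
    vi = NA_real_, sse = NA_real_, r_squared = NA_real_, runs_p = NA_real_,
    iterations = NA_integer_, converged_by = NA_character_,
    degenerate = NA, note = NA_character_
  )
  if (length(cycles) < spec$n_params + 1) {
    base$note <- "too_short"
    return(base)
  }
  fit <- tryCatch(
    fit_series(cycles, signals, model, control = control),
    error = function(e) conditionMessage(e)
  )
  if (is.character(fit)) {
    base$note <- paste0("error: ", fit)
    return(base)
  }
  for (nm in names(fit$params)) base[[nm]] <- fit$params[[nm]]
  base$sse <- fit$sse
  base$r_squared <- fit$r_squared
  base$runs_p <- fit$runs_p
  base$iterations <- as.integer(fit$iterations)
  base$converged_by <- fit$converged_by
  base$degenerate <- fit$degenerate
  base
}

empty_fit_tbl <- function() {
  tibble::tibble(
    sample_id = character(), peptide_id = character(), model = character(),
    y0 = numeric(), ymax = numeric(), k = numeric(), c0 = numeric(),
    vi = numeric(), sse = numeric(), r_squared = numeric(),
    runs_p = numeric(), iterations = integer(), converged_by = character(),
    degenerate = logical(), note = character()
  )
}

as_kin_long <- function(data) {
  need <- c("peptide_id", "cycle", "signal")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("data must have columns ", paste(need, collapse = ", "),
      "; missing ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) data$sample_id <- "sample1"
  data
}
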