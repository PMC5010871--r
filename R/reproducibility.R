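# Technical-replicate reproducibility: quantile transformation of parameter
# estimates, quantile-quantile rank correlations, kernel density summaries.

#' Quantile transformation of parameter estimates
#'
#' Replaces raw values by their empirical quantiles, `rank / n`, with
#' average ranks for ties. Order-preserving, and maps into (0, 1].
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return Numeric vector of quantiles, same length.
#' @examples
#' quantile_transform(c(10, 30, 20)) # 1/3, 1, 2/3
#' @export
quantile_transform <- function(values) {
  if (length(values) < 2 || any(!is.finite(values))) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  rank(values, ties.method = "average") / length(values)
}

#' Quantile-quantile correlation of paired replicate estimates
#'
#' Spearman rank correlation of paired parameter estimates from technical
#' replicates; identical to Pearson correlation of the quantile-transformed
#' values when ties are absent.
#'
#' @param a,b Equal-length numeric vectors (length >= 3) of paired
#'   estimates (raw or quantile-transformed; the result is the same).
#' @return Correlation in \[-1, 1\]; `NA` with a warning for constant input.
#' @export
qq_correlation <- function(a, b) {
  if (length(a) != length(b)) {
    stop("a and b must have equal length", call. = FALSE)
  }
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("correlation undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Extract paired replicate parameter estimates
#'
#' Builds all unordered within-set replicate pairs of a fitted parameter,
#' restricted to peptides whose fit passed the runs-test QC (at `alpha`,
#' for the model in question) in both members of the pair. `v_ini` is
#' computed from the eq2 parameters via [v_ini()] before pairing.
#'
#' Replicates are identified by `sample_id`; an optional `replicate_set`
#' column in `fits` restricts pairing to within-set pairs (pairs across
#' sets are never formed).
#'
#' @param fits Fit table from [fit_kinetics()] over a replicated dataset.
#' @param model Model id supplying the parameter (`"eq2"` for `k`, `ymax`,
#'   `v_ini`; `"eq3"` for `vi`, `ymax`).
#' @param parameter One of `"k"`, `"ymax"`, `"vi"`, `"v_ini"`.
#' @param alpha Per-model QC threshold on the runs-test p-value.
#' @param c_eval Evaluation cycle for `v_ini` (default 35).
#' @return Tibble with columns `replicate_set`, `peptide_id`, `rep_a`,
#'   `rep_b`, `value_a`, `value_b`; zero rows (with a warning) when no pair
#'   survives QC.
#' @export
pair_replicates <- function(fits, model, parameter = c("k", "ymax", "vi", "v_ini"),
                            alpha = 0.05, c_eval = 35) {
  parameter <- match.arg(parameter)
  model <- match.arg(model, kin_models)
  if (parameter == "v_ini" && model != "eq2") {
    stop("v_ini is computed from eq2 fits", call. = FALSE)
  }
  if (parameter %in% c("k", "vi") &&
    !parameter %in% kin_param_names[[model]]) {
    stop("parameter ", parameter, " does not belong to model ", model,
      call. = FALSE
    )
  }
  fits <- tibble::as_tibble(fits)
  if (!"replicate_set" %in% names(fits)) fits$replicate_set <- "set1"

  keep <- fits |>
    dplyr::filter(
      .data$model == !!model,
      !is.na(.data$runs_p), .data$runs_p >= alpha,
      !.data$degenerate
    ) |>
    dplyr::mutate(
      value = if (parameter == "v_ini") {
        v_ini_vec(.data$ymax, .data$k, .data$c0, c_eval)
      } else {
        .data[[parameter]]
      }
    ) |>
    dplyr::select(
      "replicate_set", "peptide_id", "sample_id", "value"
    )

  pairs <- keep |>
    dplyr::inner_join(
      keep,
      by = c("replicate_set", "peptide_id"),
      suffix = c("_a", "_b"),
      relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$sample_id_a < .data$sample_id_b) |>
    dplyr::select(
      "replicate_set", "peptide_id",
      rep_a = "sample_id_a", rep_b = "sample_id_b",
      value_a = "value_a", value_b = "value_b"
    )
  if (nrow(pairs) == 0) {
    warning("no replicate pairs survive the QC filter", call. = FALSE)
  }
  pairs
}

v_ini_vec <- function(ymax, k, c0, c_eval) {
  ymax * k * exp(-k * (c_eval - c0))
}

#' Replicate reproducibility of one fitted parameter
#'
#' Convenience wrapper: [pair_replicates()], quantile transformation of the
#' pooled pair columns, then the quantile-quantile Spearman correlation.
#'
#' @inheritParams pair_replicates
#' @return One-row tibble: `model`, `parameter`, `n_pairs`, `correlation`.
#' @examples
#' chip <- simulate_chip(chip_sim_config(
#'   n_peptides = 20, n_replicates = 4, seed = 3
#' ))
#' fits <- fit_kinetics(chip$data, models = c("eq2", "eq3"))
#' replicate_correlation(fits, "eq3", "vi")
#' @export
replicate_correlation <- function(fits, model, parameter, alpha = 0.05,
                                  c_eval = 35) {
  pairs <- pair_replicates(fits, model, parameter, alpha, c_eval)
  corr <- if (nrow(pairs) >= 3) {
    qq_correlation(
      quantile_transform(pairs$value_a),
      quantile_transform(pairs$value_b)
    )
  } else {
    NA_real_
  }
  tibble::tibble(
    model = model, parameter = parameter,
    n_pairs = nrow(pairs), correlation = corr
  )
}

#' Rule-of-thumb Gaussian kernel density estimate
#'
#' Parzen-Rosenblatt estimator with the Gaussian rule-of-thumb bandwidth
#' `h = 1.06 * sd(values) * n^(-1/5)`, evaluated on a caller-supplied grid.
#'
#' @param values Numeric sample (>= 2 distinct values).
#' @param grid Numeric evaluation grid; defaults to 512 points spanning the
#'   sample range extended by 3 bandwidths.
#' @param bw Optional bandwidth override.
#' @return Tibble with columns `x` (grid) and `density`.
#' @export
kde_density <- function(values, grid = NULL, bw = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2 || stats::sd(values) == 0) {
    stop("density undefined: need >= 2 distinct values", call. = FALSE)
  }
  h <- if (is.null(bw)) 1.06 * stats::sd(values) * n^(-1 / 5) else bw
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = 512)
  }
  dens <- vapply(
    grid,
    function(x) mean(stats::dnorm((x - values) / h)) / h,
    numeric(1)
  )
  tibble::tibble(x = grid, density = dens)
}

# Product-kernel 2-D extension of the same rule-of-thumb KDE, evaluated at
# the observation points themselves; used only to colour replicate
# scatter plots by local density.
kde2d_at_points <- function(x, y) {
  n <- length(x)
  hx <- 1.06 * stats::sd(x) * n^(-1 / 5)
  hy <- 1.06 * stats::sd(y) * n^(-1 / 5)
  if (hx == 0 || hy == 0) {
    return(rep(NA_real_, n))
  }
  vapply(seq_len(n), function(i) {
    mean(stats::dnorm((x[i] - x) / hx) * stats::dnorm((y[i] - y) / hy)) /
      (hx * hy)
  }, numeric(1))
}
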