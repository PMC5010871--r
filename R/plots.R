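# ggplot2 graphics for fits, residual densities and replicate scatter.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one fitted progress curve
#'
#' Observed points with the fitted model curve evaluated on a fine cycle
#' grid.
#'
#' @param object A `kin_fit` from [fit_series()].
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_fit <- function(object, n_grid = 200, ...) {
  grid <- seq(min(object$cycles), max(object$cycles), length.out = n_grid)
  curve <- tibble::tibble(
    cycle = grid,
    signal = eval_kinetic(object$model, object$params, grid)
  )
  pts <- tibble::tibble(cycle = object$cycles, signal = object$signals)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$cycle, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(
      x = "cycle", y = "background-subtracted signal",
      title = paste0(
        object$model, " fit (R² = ",
        sprintf("%.3f", object$r_squared),
        ", runs p = ", sprintf("%.3f", object$runs_p), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Overlay fitted curves for selected peptides
#'
#' @param data Long series table (`sample_id`, `peptide_id`, `cycle`,
#'   `signal`).
#' @param fits Fit table from [fit_kinetics()].
#' @param peptides Peptide ids to show (default: first 6).
#' @param models Models to draw.
#' @return A faceted ggplot object.
#' @export
plot_fit_curves <- function(data, fits, peptides = NULL,
                            models = kin_models) {
  data <- as_kin_long(data)
  if (is.null(peptides)) {
    peptides <- utils::head(unique(data$peptide_id), 6)
  }
  data <- dplyr::filter(data, .data$peptide_id %in% peptides)
  fits <- dplyr::filter(
    tibble::as_tibble(fits),
    .data$peptide_id %in% peptides, .data$model %in% models,
    !is.na(.data$sse)
  )
  grid <- seq(min(data$cycle), max(data$cycle), length.out = 100)
  curves <- fits |>
    dplyr::rowwise() |>
    dplyr::reframe(
      sample_id = .data$sample_id, peptide_id = .data$peptide_id,
      model = .data$model, cycle = grid,
      signal = eval_kinetic(
        .data$model,
        c(
          y0 = .data$y0, ymax = .data$ymax, k = .data$k,
          c0 = .data$c0, vi = .data$vi
        ),
        grid
      )
    )
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cycle, y = .data$signal)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$model, group = interaction(
        .data$sample_id, .data$model
      ))
    ) +
    ggplot2::facet_wrap(~peptide_id, scales = "free_y") +
    ggplot2::labs(x = "cycle", y = "background-subtracted signal") +
    ggplot2::theme_minimal()
}

#' Residual density by model
#'
#' Rule-of-thumb KDE of fit residual SD-scaled deviations per model; the
#' model whose residual density peaks highest concentrates its residuals
#' most tightly around zero.
#'
#' @param fits Fit table from [fit_kinetics()].
#' @param value Column to summarise (default `"sse"`).
#' @return A ggplot object.
#' @export
plot_density_by_model <- function(fits, value = "sse") {
  fits <- dplyr::filter(tibble::as_tibble(fits), is.finite(.data[[value]]))
  dens <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(~ kde_density(.x[[value]])) |>
    dplyr::ungroup()
  ggplot2::ggplot(dens, ggplot2::aes(
    x = .data$x, y = .data$density, colour = .data$model
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = value, y = "density") +
    ggplot2::theme_minimal()
}

#' Replicate agreement scatter on the quantile scale
#'
#' Quantile-transformed paired replicate estimates against the identity
#' line, coloured by local 2-D kernel density (product-kernel extension of
#' the rule-of-thumb KDE).
#'
#' @param pairs Pair table from [pair_replicates()].
#' @return A ggplot object.
#' @export
plot_replicate_pairs <- function(pairs) {
  stopifnot(nrow(pairs) >= 3)
  qa <- quantile_transform(pairs$value_a)
  qb <- quantile_transform(pairs$value_b)
  df <- tibble::tibble(
    qa = qa, qb = qb, dens = kde2d_at_points(qa, qb)
  )
  rho <- qq_correlation(qa, qb)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$qa, y = .data$qb, colour = .data$dens
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_viridis_c(option = "inferno", name = "density") +
    ggplot2::labs(
      x = "replicate A quantile", y = "replicate B quantile",
      title = sprintf("Spearman q-q correlation = %.4f", rho)
    ) +
    ggplot2::theme_minimal()
}
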