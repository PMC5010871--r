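# Synthetic chip generator: kinomic-array-like datasets with known ground
# truth, so fitting, QC and reproducibility analyses are testable without
# instrument data.

#' Synthetic chip configuration
#'
#' Defines the conditions a simulated chip emulates: 144 peptides read at
#' 13 reaction cycles, per-peptide kinetic truth drawn from log-uniform
#' priors, additive homoscedastic Gaussian noise on the
#' background-subtracted signal (which may therefore go negative), a
#' fraction of peptides left in the near-linear regime (capacity far above
#' the achievable signal range), and technical replicates sharing the
#' per-peptide truth with independent noise. The seed fully determines the
#' output.
#'
#' @param n_peptides Peptides per chip (default 144).
#' @param cycles Strictly increasing cycle grid (default 13 points,
#'   `seq(5, 65, by = 5)`).
#' @param true_model Generating model, one of [kin_models] (default
#'   `"eq3"`).
#' @param ymax_range,vi_range,k_range Log-uniform prior ranges for
#'   capacity, hyperbolic initial rate, and exponential rate.
#' @param c0_range,y0_range Uniform prior ranges for the cycle offset and
#'   the exponential baseline.
#' @param noise_sd Additive Gaussian noise SD in signal units (default 12,
#'   about 2% of the median capacity under the default prior).
#' @param fraction_linear_phase Proportion of peptides whose capacity is
#'   redrawn to 10-100x the achievable signal range, so their curves stay
#'   near-linear over the observed cycles (default 0.25).
#' @param linear_multiplier_range Log-uniform range of that redraw
#'   multiplier.
#' @param n_replicates Technical replicates sharing the truth (default 1).
#' @param seed Integer seed (default 1).
#' @return An object of class `kin_sim_config` (a validated list).
#' @export
chip_sim_config <- function(n_peptides = 144,
                            cycles = seq(5, 65, by = 5),
                            true_model = "eq3",
                            ymax_range = c(200, 2000),
                            vi_range = c(1, 50),
                            k_range = c(0.01, 0.1),
                            c0_range = c(0, 5),
                            y0_range = c(0, 20),
                            noise_sd = 12,
                            fraction_linear_phase = 0.25,
                            linear_multiplier_range = c(10, 100),
                            n_replicates = 1,
                            seed = 1) {
  true_model <- match.arg(true_model, kin_models)
  stopifnot(
    n_peptides >= 1, length(cycles) >= 2, all(diff(cycles) > 0),
    noise_sd >= 0, fraction_linear_phase >= 0, fraction_linear_phase <= 1,
    n_replicates >= 1
  )
  structure(
    list(
      n_peptides = as.integer(n_peptides), cycles = cycles,
      true_model = true_model, ymax_range = ymax_range,
      vi_range = vi_range, k_range = k_range, c0_range = c0_range,
      y0_range = y0_range, noise_sd = noise_sd,
      fraction_linear_phase = fraction_linear_phase,
      linear_multiplier_range = linear_multiplier_range,
      n_replicates = as.integer(n_replicates), seed = as.integer(seed)
    ),
    class = "kin_sim_config"
  )
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Simulate one peptide time series
#'
#' Model curve plus iid additive Gaussian noise; negative signals are
#' retained, as background subtraction can undershoot on a real chip.
#'
#' @param config A [chip_sim_config()] (supplies cycles, model and noise).
#' @param true_params Named numeric vector of generating parameters.
#' @param peptide_id,sample_id Identifiers attached to the output.
#' @return Tibble with columns `sample_id`, `peptide_id`, `cycle`,
#'   `signal`. Uses (and advances) the current RNG state; seed at the call
#'   site or use [simulate_chip()] for seeded output.
#' @export
simulate_series <- function(config, true_params, peptide_id = "p001",
                            sample_id = "rep01") {
  truth <- eval_kinetic(config$true_model, true_params, config$cycles)
  tibble::tibble(
    sample_id = sample_id,
    peptide_id = peptide_id,
    cycle = config$cycles,
    signal = truth + stats::rnorm(length(truth), 0, config$noise_sd)
  )
}

#' Simulate a whole replicated chip
#'
#' Draws per-peptide true parameters from the configured priors, redraws
#' the capacity of a `fraction_linear_phase` subset to far exceed the
#' achievable signal range (near-linear curves), then emits
#' `n_replicates` technical replicates per peptide: shared truth,
#' independent noise. Fully reproducible from `config$seed`.
#'
#' @param config A [chip_sim_config()].
#' @return An object of class `kin_sim`: list with `data` (long tibble:
#'   `sample_id`, `peptide_id`, `cycle`, `signal`), `truth` (tibble of
#'   generating parameters per peptide, with `linear_phase` flag) and
#'   `config`.
#' @examples
#' chip <- simulate_chip(chip_sim_config(n_peptides = 5, seed = 42))
#' chip$truth
#' @export
simulate_chip <- function(config = chip_sim_config()) {
  stopifnot(inherits(config, "kin_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_peptides
    ids <- sprintf("p%03d", seq_len(n))
    truth <- switch(config$true_model,
      eq1 = tibble::tibble(
        peptide_id = ids,
        y0 = stats::runif(n, config$y0_range[1], config$y0_range[2]),
        ymax = runif_log(n, config$ymax_range),
        k = runif_log(n, config$k_range)
      ),
      eq2 = tibble::tibble(
        peptide_id = ids,
        y0 = stats::runif(n, config$y0_range[1], config$y0_range[2]),
        ymax = runif_log(n, config$ymax_range),
        k = runif_log(n, config$k_range),
        c0 = stats::runif(n, config$c0_range[1], config$c0_range[2])
      ),
      eq3 = tibble::tibble(
        peptide_id = ids,
        ymax = runif_log(n, config$ymax_range),
        vi = runif_log(n, config$vi_range),
        c0 = stats::runif(n, config$c0_range[1], config$c0_range[2])
      )
    )
    n_lin <- round(config$fraction_linear_phase * n)
    truth$linear_phase <- FALSE
    if (n_lin > 0) {
      lin_idx <- sample.int(n, n_lin)
      truth$linear_phase[lin_idx] <- TRUE
      cmax <- max(config$cycles)
      mult <- runif_log(n_lin, config$linear_multiplier_range)
      # achievable range: signal a pure linear accumulation would reach
      rate <- if (config$true_model == "eq3") truth$vi[lin_idx] else {
        truth$ymax[lin_idx] * truth$k[lin_idx]
      }
      c0 <- if (config$true_model == "eq1") 0 else truth$c0[lin_idx]
      truth$ymax[lin_idx] <- mult * pmax(rate * (cmax - c0), 1)
    }
    pnames <- kin_param_names[[config$true_model]]
    data <- purrr::map(seq_len(config$n_replicates), function(r) {
      sample_id <- sprintf("rep%02d", r)
      purrr::map(seq_len(n), function(i) {
        simulate_series(
          config,
          stats::setNames(as.numeric(truth[i, pnames]), pnames),
          peptide_id = ids[i], sample_id = sample_id
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    structure(
      list(data = data, truth = truth, config = config),
      class = "kin_sim"
    )
  })
}

#' @export
print.kin_sim <- function(x, ...) {
  cat("<kin_sim> ", x$config$n_peptides, " peptides x ",
    x$config$n_replicates, " replicate(s), ",
    length(x$config$cycles), " cycles, model ", x$config$true_model,
    ", noise sd ", x$config$noise_sd, ", seed ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}
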