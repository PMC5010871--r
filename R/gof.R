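# Goodness of fit: R-squared, the Wald-Wolfowitz runs test on residual
# signs, and the quality-control gate built on it.

#' Coefficient of determination
#'
#' `1 - SSE / SStot` with the total sum of squares taken about the signal
#' mean. May be negative for fits worse than the mean; undefined (NA, with
#' a warning) when the observed signals have zero variance.
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @return Single numeric.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) {
    stop("observed and fitted must have equal length", call. = FALSE)
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    warning("R-squared undefined: observed signals have zero variance",
      call. = FALSE
    )
    return(NA_real_)
  }
  1 - sum((observed - fitted)^2) / sstot
}

#' Exact distribution of the number of runs
#'
#' Probability mass function of the run count conditional on `n1` positive
#' and `n2` negative signs, under the null that all `choose(n1 + n2, n1)`
#' arrangements are equally likely.
#'
#' @param n1,n2 Counts of positive and negative signs (both >= 1).
#' @return A tibble with columns `runs` and `prob`, covering
#'   `2:(n1 + n2)` (probability 0 where a run count is unattainable).
#' @export
runs_distribution <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  n <- n1 + n2
  total <- choose(n, n1)
  runs <- 2:n
  prob <- vapply(runs, function(r) {
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / total
    } else {
      k <- (r - 1) / 2
      (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / total
    }
  }, numeric(1))
  tibble::tibble(runs = runs, prob = prob)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' One-sided lack-of-fit test: systematic misfit shows up as long stretches
#' of same-sign residuals, i.e. too few runs. Returns
#' `P(runs <= observed)` under the exact conditional distribution of run
#' counts given the sign counts when `n1 + n2 <= exact_limit`; beyond that
#' a normal approximation with continuity correction is used
#' (mean `1 + 2 n1 n2 / n`, variance
#' `2 n1 n2 (2 n1 n2 - n) / (n^2 (n - 1))`).
#'
#' Zero residuals are dropped before counting signs. Degenerate inputs
#' (all residuals zero, or all of one sign so that the conditional
#' distribution is a point mass at one run) return p = 1 with a warning.
#'
#' @param residuals Numeric vector of residuals (observed - fitted).
#' @param exact_limit Largest `n1 + n2` handled exactly (default 30).
#' @return Single numeric p-value in (0, 1], with attributes `n_pos`,
#'   `n_neg`, `runs` and `method`.
#' @examples
#' runs_test(c(1, 2, 3, -1, -2, -3)) # two runs of three: p = 0.1
#' @export
runs_test <- function(residuals, exact_limit = 30) {
  signs <- sign(residuals[residuals != 0])
  n1 <- sum(signs > 0)
  n2 <- sum(signs < 0)
  if (length(signs) == 0) {
    warning("all residuals are zero: runs test degenerate, p = 1",
      call. = FALSE
    )
    return(structure(1, n_pos = 0L, n_neg = 0L, runs = 0L,
      method = "degenerate"
    ))
  }
  r_obs <- 1L + sum(signs[-1] != signs[-length(signs)])
  if (n1 == 0 || n2 == 0) {
    # one-sign sequences: the conditional law is a point mass at one run
    warning("all residuals share one sign: runs test degenerate, p = 1",
      call. = FALSE
    )
    return(structure(1, n_pos = n1, n_neg = n2, runs = r_obs,
      method = "degenerate"
    ))
  }
  if (n1 + n2 <= exact_limit) {
    dist <- runs_distribution(n1, n2)
    p <- sum(dist$prob[dist$runs <= r_obs])
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- 1 + 2 * n1 * n2 / n
    sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    p <- stats::pnorm((r_obs - mu + 0.5) / sqrt(sigma2))
    method <- "normal"
  }
  structure(min(p, 1), n_pos = n1, n_neg = n2, runs = r_obs, method = method)
}

#' Quality-control gate on fitted models
#'
#' Applies the runs-test rule: a model passes for a peptide when its
#' runs-test p-value is at least `alpha`; a peptide passes jointly only
#' when all three models were fitted and all pass. Degenerate or failed
#' fits count as failures with a reason.
#'
#' @param fits Fit table from [fit_kinetics()] (or [tidy()] of a pipeline).
#' @param alpha Pass threshold on the runs-test p-value (default 0.05).
#' @return A tibble of class `kin_qc`, one row per (sample, peptide):
#'   `runs_p_eq1..3`, `pass_eq1..3`, `n_models`, `pass_all`, `reason`
#'   (`"ok"`, `"incomplete"` or `"runs_test"`).
#' @examples
#' chip <- simulate_chip(chip_sim_config(n_peptides = 4, seed = 11))
#' fits <- fit_kinetics(chip$data)
#' qc_gate(fits)
#' @export
qc_gate <- function(fits, alpha = 0.05) {
  stopifnot(is.data.frame(fits), alpha >= 0, alpha <= 1)
  if (nrow(fits) == 0) {
    out <- tibble::tibble(
      sample_id = character(), peptide_id = character(),
      runs_p_eq1 = numeric(), runs_p_eq2 = numeric(), runs_p_eq3 = numeric(),
      pass_eq1 = logical(), pass_eq2 = logical(), pass_eq3 = logical(),
      n_models = integer(), pass_all = logical(), reason = character()
    )
    return(structure(out, class = c("kin_qc", class(out)), alpha = alpha))
  }
  long <- fits |>
    dplyr::mutate(
      pass = !is.na(.data$runs_p) & .data$runs_p >= alpha &
        !isTRUE(.data$degenerate)
    ) |>
    dplyr::select(
      "sample_id", "peptide_id", "model", "runs_p", "pass"
    )
  wide <- tidyr::pivot_wider(
    long,
    names_from = "model",
    values_from = c("runs_p", "pass"),
    names_sep = "_"
  )
  for (m in kin_models) {
    pcol <- paste0("runs_p_", m)
    bcol <- paste0("pass_", m)
    if (!pcol %in% names(wide)) wide[[pcol]] <- NA_real_
    if (!bcol %in% names(wide)) wide[[bcol]] <- NA
  }
  out <- wide |>
    dplyr::mutate(
      n_models = rowSums(!is.na(cbind(
        .data$runs_p_eq1, .data$runs_p_eq2, .data$runs_p_eq3
      ))),
      pass_all = .data$n_models == 3L &
        dplyr::coalesce(.data$pass_eq1, FALSE) &
        dplyr::coalesce(.data$pass_eq2, FALSE) &
        dplyr::coalesce(.data$pass_eq3, FALSE),
      reason = dplyr::case_when(
        .data$n_models < 3 ~ "incomplete",
        .data$pass_all ~ "ok",
        TRUE ~ "runs_test"
      )
    ) |>
    dplyr::select(
      "sample_id", "peptide_id",
      "runs_p_eq1", "runs_p_eq2", "runs_p_eq3",
      "pass_eq1", "pass_eq2", "pass_eq3",
      "n_models", "pass_all", "reason"
    )
  structure(out, class = c("kin_qc", class(out)), alpha = alpha)
}
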