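# Coordinate-descent least squares: SSE, descent behavior, oracle
# equivalence, invariances.

test_that("sse matches hand computation", {
  cyc <- 1:5
  p <- c(y0 = 1, ymax = 10, k = 0.2)
  f <- eval_kinetic("eq1", p, cyc)
  expect_equal(sse_kinetic("eq1", p, cyc, f), 0)
  expect_equal(
    sse_kinetic("eq1", p, cyc, f - c(1, -2, 3, 0, 0)), 14
  )
  expect_equal(sse_kinetic("eq1", p, cyc[1], f[1] + 3), 9)
})

test_that("noiseless hyperbolic data are recovered from algebraic starts", {
  cyc <- 1:13
  truth <- c(ymax = 100, vi = 2, c0 = 0)
  sig <- eval_kinetic("eq3", truth, cyc)
  fit <- fit_series(cyc, sig, "eq3")
  expect_lt(abs(fit$params[["vi"]] - 2) / 2, 0.01)
  expect_lt(fit$sse, 1e-6 * sum(sig^2))
  expect_lte(fit$sse, sse_kinetic("eq3", fit$init, cyc, sig))
})

test_that("a globally optimal start terminates immediately, unchanged", {
  cyc <- 1:13
  truth <- c(ymax = 100, vi = 2, c0 = 0)
  sig <- eval_kinetic("eq3", truth, cyc)
  fit <- suppressWarnings(fit_series(cyc, sig, "eq3", init = truth))
  expect_equal(fit$params, truth)
  expect_equal(fit$sse, 0)
  expect_equal(fit$converged_by, "SSE_CHANGE")
  expect_equal(fit$iterations, 1L)
})

test_that("the fitter matches a dense grid-search oracle on a line model", {
  set.seed(77)
  for (i in 1:5) {
    cyc <- 1:13
    a <- runif(1, -5, 5)
    b <- runif(1, 0.5, 3)
    y <- a + b * cyc + rnorm(13, 0, 0.5)
    obj <- function(p) sum((p[1] + p[2] * cyc - y)^2)
    fit <- coord_descent(obj, c(y[1], (y[2] - y[1])))
    gmin <- grid_min_sse(obj, a + c(-2, 2), b + c(-1, 1))
    expect_lte(fit$sse, 1.01 * gmin)
  }
})

test_that("results scale with the signal for y-dimension parameters", {
  cyc <- 1:13
  truth <- c(ymax = 150, vi = 4, c0 = 1)
  sig <- eval_kinetic("eq3", truth, cyc)
  f1 <- fit_series(cyc, sig, "eq3")
  f2 <- fit_series(cyc, sig * 7, "eq3")
  expect_equal(f2$params[["ymax"]] / f1$params[["ymax"]], 7, tolerance = 1e-3)
  expect_equal(f2$params[["vi"]] / f1$params[["vi"]], 7, tolerance = 1e-3)
  expect_equal(f2$params[["c0"]], f1$params[["c0"]], tolerance = 1e-3)
})

test_that("the algorithm is deterministic", {
  cyc <- seq(5, 65, by = 5)
  set.seed(9)
  sig <- eval_kinetic("eq3", c(ymax = 300, vi = 8, c0 = 2), cyc) + rnorm(13, 0, 10)
  f1 <- fit_series(cyc, sig, "eq3")
  f2 <- fit_series(cyc, sig, "eq3")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$iterations, f2$iterations)
})

test_that("compiled and generic engines implement the same algorithm", {
  cyc <- seq(5, 65, by = 5)
  set.seed(10)
  for (m in kin_models) {
    truth <- switch(m,
      eq1 = c(y0 = 5, ymax = 400, k = 0.05),
      eq2 = c(y0 = 5, ymax = 400, k = 0.05, c0 = 3),
      eq3 = c(ymax = 400, vi = 10, c0 = 3)
    )
    sig <- eval_kinetic(m, truth, cyc) + rnorm(13, 0, 8)
    fc <- fit_series(cyc, sig, m, engine = "cpp")
    fr <- fit_series(cyc, sig, m, engine = "r")
    expect_equal(fc$params, fr$params, tolerance = 1e-10)
    expect_equal(fc$sse, fr$sse, tolerance = 1e-10)
    expect_identical(fc$iterations, fr$iterations)
  }
})

test_that("non-finite proposals are rejected, not fatal", {
  # objective undefined left of 0: the search stays in the feasible region
  obj <- function(p) {
    if (p[1] <= 0) {
      return(NaN)
    }
    (log(p[1]) - 1)^2
  }
  fit <- coord_descent(obj, 0.5)
  expect_true(is.finite(fit$sse))
  expect_equal(fit$par[[1]], exp(1), tolerance = 1e-2)
  expect_error(coord_descent(function(p) NaN, 1), "invalid start")
})

test_that("fit_all_models is structurally complete and length-aware", {
  cyc <- seq(5, 65, by = 5)
  set.seed(11)
  sig <- eval_kinetic("eq2", c(y0 = 5, ymax = 300, k = 0.05, c0 = 3), cyc) +
    rnorm(13, 0, 5)
  fits <- fit_all_models(cyc, sig)
  expect_named(fits, c("eq1", "eq2", "eq3"))

  # noiseless generating model is recovered essentially exactly
  clean <- eval_kinetic("eq2", c(y0 = 5, ymax = 300, k = 0.05, c0 = 3), cyc)
  f2 <- fit_all_models(cyc, clean)[["eq2"]]
  expect_lt(f2$sse, 1e-6 * sum(clean^2))

  # 4 points: the 4-parameter model needs 5, the 3-parameter models fit
  expect_message(
    short <- fit_all_models(cyc[1:4], sig[1:4]),
    "skipping eq2"
  )
  expect_named(short, c("eq1", "eq3"))
})

test_that("fit_kinetics returns one tidy row per (sample, peptide, model)", {
  chip <- simulate_chip(chip_sim_config(
    n_peptides = 3, n_replicates = 2, seed = 12
  ))
  fits <- fit_kinetics(chip$data)
  expect_s3_class(fits, "tbl_df")
  expect_equal(nrow(fits), 3 * 2 * 3)
  expect_equal(
    dplyr::count(fits, sample_id, peptide_id)$n,
    rep(3, 6)
  )
  expect_true(all(is.finite(fits$sse)))
  # hyperbolic rows carry vi, exponential rows carry k
  expect_true(all(is.na(fits$vi[fits$model != "eq3"])))
  expect_true(all(is.finite(fits$k[fits$model != "eq3"])))
})

test_that("fit_control validates its arguments", {
  expect_error(fit_control(max_iterations = 0))
  expect_error(fit_control(min_sse_percent_change = 0))
  expect_equal(fit_control()$max_iterations, 1000L)
  expect_equal(fit_control()$min_sse_percent_change, 6e-5)
  expect_equal(fit_control()$initial_step_fraction, 0.01)
})
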