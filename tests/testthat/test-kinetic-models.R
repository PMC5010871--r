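# Model evaluation, asymptotes, the early-slope statistic, the hyperbolic
# derivation identity and algebraic initialization.

test_that("model evaluation matches hand-computed values", {
  # hyperbolic: vanishes at c = c0, 10000/200 = 50 mid-curve
  expect_equal(eval_kinetic("eq3", c(ymax = 100, vi = 2, c0 = 0), 0), 0)
  expect_equal(eval_kinetic("eq3", c(ymax = 100, vi = 2, c0 = 0), 50), 50)
  # background-corrected exponential returns the baseline at c = c0
  expect_equal(
    eval_kinetic("eq2", c(y0 = 5, ymax = 100, k = 0.3, c0 = 10), 10), 5
  )
  # simple exponential at c = 0 is the baseline
  expect_equal(eval_kinetic("eq1", c(y0 = 2, ymax = 10, k = 0.5), 0), 2)
})

test_that("evaluation is vectorized and unclamped below c0", {
  p <- c(ymax = 100, vi = 2, c0 = 10)
  y <- eval_kinetic("eq3", p, c(5, 10, 15))
  expect_length(y, 3)
  expect_lt(y[1], 0) # evaluated as written, no clamping
  expect_equal(y[2], 0)
})

test_that("a vanishing hyperbolic denominator signals degenerate parameters", {
  # ymax + vi*(c - c0) = 0 at c = 50 for these values
  expect_error(
    eval_kinetic("eq3", c(ymax = 100, vi = -2, c0 = 0), 50),
    "degenerate"
  )
})

test_that("asymptotic limits are y0 + ymax (exponential) and ymax (hyperbolic)", {
  expect_equal(model_limit("eq3", c(ymax = 100, vi = 2, c0 = 0)), 100)
  expect_equal(model_limit("eq2", c(y0 = 5, ymax = 100, k = 0.1, c0 = 0)), 105)
  expect_equal(model_limit("eq1", c(y0 = 0, ymax = 1, k = 1)), 1)
  expect_warning(
    lim <- model_limit("eq3", c(ymax = 100, vi = -1, c0 = 0)),
    "non-positive rate"
  )
  expect_true(is.na(lim))
})

test_that("hyperbolic limit is the supremum of the curve within 0.1%", {
  set.seed(41)
  for (i in 1:20) {
    p <- c(
      ymax = exp(runif(1, log(10), log(5000))),
      vi = exp(runif(1, log(0.1), log(50))),
      c0 = runif(1, 0, 5)
    )
    sup <- max(eval_kinetic(
      "eq3", p, seq(p[["c0"]] + 1e-6, 1e9, length.out = 2000)
    ))
    expect_lt(abs(model_limit("eq3", p) - sup) / sup, 1e-3)
  }
})

test_that("all models are monotone non-decreasing past c0 for positive rates", {
  set.seed(42)
  cyc <- seq(0, 80, by = 0.5)
  for (i in 1:25) {
    ymax <- exp(runif(1, log(10), log(2000)))
    k <- exp(runif(1, log(1e-3), log(0.5)))
    vi <- exp(runif(1, log(0.1), log(50)))
    c0 <- runif(1, 0, 5)
    y0 <- runif(1, -10, 10)
    for (case in list(
      list("eq1", c(y0 = y0, ymax = ymax, k = k), 0),
      list("eq2", c(y0 = y0, ymax = ymax, k = k, c0 = c0), c0),
      list("eq3", c(ymax = ymax, vi = vi, c0 = c0), c0)
    )) {
      cc <- cyc[cyc >= case[[3]]]
      expect_true(all(diff(eval_kinetic(case[[1]], case[[2]], cc)) >= 0))
    }
  }
})

test_that("v_ini matches hand values and the finite-difference derivative", {
  expect_equal(v_ini(c(ymax = 100, k = 0.1, c0 = 35)), 10)
  expect_equal(v_ini(c(ymax = 100, k = 0, c0 = 0)), 0)
  expect_equal(
    v_ini(c(ymax = 50, k = 0.05, c0 = 5)), 50 * 0.05 * exp(-1.5)
  )
  # derivative of the eq2 curve at the evaluation cycle, k in [1e-3, 1];
  # c0 near c_eval keeps the curve from flat-lining below the precision a
  # finite difference of the signal can resolve
  for (k in c(1e-3, 0.01, 0.05, 0.2, 1)) {
    p <- c(y0 = 7, ymax = 120, k = k, c0 = 30)
    fd <- fd_derivative(function(c) eval_kinetic("eq2", p, c), 35)
    expect_lt(abs(v_ini(p) - fd) / abs(fd), 1e-6)
  }
})

test_that("v_ini evaluation cycle is a parameter", {
  p <- c(ymax = 80, k = 0.04, c0 = 2)
  fd <- fd_derivative(function(c) eval_kinetic("eq2", c(p, y0 = 0), c), 20)
  expect_equal(v_ini(p, c_eval = 20), fd, tolerance = 1e-6)
})

test_that("hyperbolic form and reciprocal form are the same function", {
  expect_equal(eq3_reciprocal(c(ymax = 100, vi = 2, c0 = 0), 50), 50)
  # near-linear regime: y approaches vi * (c - c0)
  expect_equal(
    eq3_reciprocal(c(ymax = 1e9, vi = 2, c0 = 0), 10), 20,
    tolerance = 1e-7
  )
  set.seed(43)
  n <- 500
  ymax <- exp(runif(n, log(1), log(1e6)))
  vi <- exp(runif(n, log(1e-3), log(1e3)))
  c0 <- runif(n, 0, 10)
  cc <- c0 + exp(runif(n, log(1e-3), log(1e3)))
  for (i in seq_len(n)) {
    p <- c(ymax = ymax[i], vi = vi[i], c0 = c0[i])
    expect_within_ulp(
      eval_kinetic("eq3", p, cc[i]),
      eq3_reciprocal(p, cc[i])
    )
  }
  expect_error(eq3_reciprocal(c(ymax = 1, vi = 1, c0 = 5), 5), "undefined")
})

test_that("algebraic initialization lands near the truth on clean data", {
  cyc <- 1:13
  truth <- c(ymax = 100, vi = 2, c0 = 0)
  sig <- eval_kinetic("eq3", truth, cyc)
  ip <- initial_params("eq3", cyc, sig)
  expect_false(ip$degenerate)
  expect_gt(ip$params[["vi"]], truth[["vi"]] / 3)
  expect_lt(ip$params[["vi"]], truth[["vi"]] * 3)
  expect_equal(ip$params[["c0"]], 1) # first cycle
})

test_that("flat series yield floor defaults and a degenerate flag", {
  cyc <- 1:13
  ip <- initial_params("eq3", cyc, rep(0, 13))
  expect_true(ip$degenerate)
  expect_true(all(ip$params[c("ymax", "vi")] > 0))
  ip2 <- initial_params("eq2", cyc, rep(0, 13))
  expect_true(ip2$degenerate)
  expect_gt(ip2$params[["k"]], 0)
})

test_that("linear series get a capacity start above the observed maximum", {
  cyc <- 1:13
  sig <- 2 * cyc
  for (m in kin_models) {
    ip <- initial_params(m, cyc, sig)
    expect_gte(ip$params[["ymax"]], max(sig))
  }
})

test_that("initialization enforces the length precondition", {
  expect_error(initial_params("eq2", 1:4, 1:4), "too short")
  expect_silent(initial_params("eq2", 1:5, c(1, 2, 3, 4, 5)))
})

test_that("model specs expose the documented parameter order", {
  expect_equal(kinetic_model("eq1")$param_names, c("y0", "ymax", "k"))
  expect_equal(kinetic_model("eq2")$param_names, c("y0", "ymax", "k", "c0"))
  expect_equal(kinetic_model("eq3")$param_names, c("ymax", "vi", "c0"))
  expect_equal(
    vapply(kin_models, function(m) kinetic_model(m)$n_params, integer(1)),
    c(eq1 = 3L, eq2 = 4L, eq3 = 3L)
  )
})
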