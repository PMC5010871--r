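# R-squared, the exact runs test, and the QC gate.

test_that("r_squared matches hand computation and edge cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  sig <- c(4, 7, 1, 9)
  expect_equal(r_squared(sig, rep(mean(sig), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_warning(r2 <- r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r2))
})

test_that("runs-test p-values match hand-enumerated cases", {
  # two runs of three: 2 of the 20 arrangements have <= 2 runs
  expect_equal(as.numeric(runs_test(c(1, 2, 3, -1, -2, -3))), 0.1)
  # alternating signs: maximal runs, p = 1
  expect_equal(as.numeric(runs_test(c(1, -1, 1, -1, 1, -1))), 1)
  # five and five, two runs
  expect_equal(
    as.numeric(runs_test(c(rep(1, 5), rep(-1, 5)))), 2 / choose(10, 5)
  )
})

test_that("exact runs test equals exhaustive enumeration up to n = 10", {
  for (n1 in 1:9) {
    for (n2 in 1:(10 - n1)) {
      enum <- enum_runs_distribution(n1, n2)
      impl <- runs_distribution(n1, n2)
      expect_equal(impl$prob, enum$prob, tolerance = 1e-12)
      # p-value at every attainable run count
      for (r in enum$runs[enum$prob > 0]) {
        signs <- arrangement_with_runs(n1, n2, r)
        expect_equal(
          as.numeric(runs_test(signs)),
          enum_runs_pvalue(n1, n2, r),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("p is monotone in the observed run count at fixed sign counts", {
  d <- runs_distribution(6, 7)
  p <- cumsum(d$prob)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[length(p)], 1, tolerance = 1e-12)
})

test_that("degenerate residual patterns are handled with p = 1 and a warning", {
  expect_warning(p0 <- runs_test(c(0, 0, 0)), "all residuals are zero")
  expect_equal(as.numeric(p0), 1)
  expect_warning(p1 <- runs_test(c(1, 2, 3)), "share one sign")
  expect_equal(as.numeric(p1), 1)
  # zeros are dropped before counting signs
  p <- runs_test(c(1, 0, 2, 0, -1, -2))
  expect_identical(attr(p, "n_pos"), 2L)
  expect_identical(attr(p, "n_neg"), 2L)
})

test_that("the normal approximation is close to the exact tail at moderate n", {
  n1 <- 16
  n2 <- 16
  # exact formula still applies; compare against the large-n branch
  exact <- runs_test(arrangement_with_runs(n1, n2, 12), exact_limit = 40)
  approx <- runs_test(arrangement_with_runs(n1, n2, 12), exact_limit = 10)
  expect_identical(attr(exact, "method"), "exact")
  expect_identical(attr(approx, "method"), "normal")
  expect_lt(abs(as.numeric(exact) - as.numeric(approx)), 0.02)
})

test_that("the QC gate applies the joint three-model rule", {
  chip <- simulate_chip(chip_sim_config(n_peptides = 5, seed = 21))
  fits <- fit_kinetics(chip$data)

  qc <- qc_gate(fits, alpha = 0.05)
  expect_equal(nrow(qc), 5)
  expect_equal(
    qc$pass_all,
    qc$pass_eq1 & qc$pass_eq2 & qc$pass_eq3 & qc$n_models == 3
  )

  # force one model below threshold: joint fail, that model fails
  fits2 <- fits
  fits2$runs_p[fits2$model == "eq2"] <- 0.01
  qc2 <- qc_gate(fits2, alpha = 0.05)
  expect_true(all(!qc2$pass_eq2))
  expect_true(all(!qc2$pass_all))
  expect_true(all(qc2$reason == "runs_test"))

  # missing model: joint fail with reason "incomplete"
  qc3 <- qc_gate(fits[fits$model != "eq1", ], alpha = 0.05)
  expect_true(all(!qc3$pass_all))
  expect_true(all(qc3$reason == "incomplete"))

  # threshold is a parameter
  qc4 <- qc_gate(fits, alpha = 1)
  expect_true(all(!qc4$pass_all | qc4$runs_p_eq1 >= 1))
})

test_that("QC rejection under the true model is conservative at alpha 0.05", {
  # residual-sign randomness of correctly specified fits; the exact test's
  # discreteness makes rejection run below the nominal level
  set.seed(22)
  n_sim <- 300
  cyc <- seq(5, 65, by = 5)
  truth <- c(ymax = 500, vi = 12, c0 = 2)
  clean <- eval_kinetic("eq3", truth, cyc)
  rej <- vapply(seq_len(n_sim), function(i) {
    f <- fit_series(cyc, clean + rnorm(13, 0, 15), "eq3")
    f$runs_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.065)
})
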