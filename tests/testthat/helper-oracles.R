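# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive enumeration of the runs distribution: every arrangement of n1
# positive and n2 negative signs is equally likely under the null.
enum_runs_distribution <- function(n1, n2) {
  n <- n1 + n2
  pos_sets <- utils::combn(n, n1)
  runs <- apply(pos_sets, 2, function(idx) {
    s <- rep(-1L, n)
    s[idx] <- 1L
    1L + sum(s[-1] != s[-n])
  })
  tab <- table(factor(runs, levels = 2:n))
  tibble::tibble(runs = 2:n, prob = as.numeric(tab) / ncol(pos_sets))
}

enum_runs_pvalue <- function(n1, n2, r_obs) {
  d <- enum_runs_distribution(n1, n2)
  sum(d$prob[d$runs <= r_obs])
}

# Centered finite-difference derivative of a scalar function.
fd_derivative <- function(f, x, h = 1e-4) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Dense grid-search minimizer for a 2-parameter objective.
grid_min_sse <- function(objective, a_range, b_range, n_grid = 200) {
  a <- seq(a_range[1], a_range[2], length.out = n_grid)
  b <- seq(b_range[1], b_range[2], length.out = n_grid)
  best <- Inf
  for (ai in a) {
    sses <- vapply(b, function(bi) objective(c(ai, bi)), numeric(1))
    best <- min(best, min(sses))
  }
  best
}

# units-in-the-last-place style comparison
expect_within_ulp <- function(actual, expected, ulp = 4) {
  tol <- ulp * .Machine$double.eps * pmax(abs(actual), abs(expected))
  expect_true(all(abs(actual - expected) <= tol))
}

# Build one explicit sign sequence with exactly r runs from n1 positives and
# n2 negatives (r must be attainable for those counts).
arrangement_with_runs <- function(n1, n2, r) {
  if (r %% 2 == 0) {
    plus_runs <- r / 2
    minus_runs <- r / 2
    start_plus <- TRUE
  } else {
    k <- (r - 1) / 2
    if (n1 >= k + 1 && n2 >= k) {
      plus_runs <- k + 1
      minus_runs <- k
      start_plus <- TRUE
    } else {
      plus_runs <- k
      minus_runs <- k + 1
      start_plus <- FALSE
    }
  }
  plus_sizes <- c(n1 - (plus_runs - 1), rep(1, max(plus_runs - 1, 0)))
  minus_sizes <- c(n2 - (minus_runs - 1), rep(1, max(minus_runs - 1, 0)))
  out <- numeric(0)
  i <- 1
  j <- 1
  for (t in seq_len(r)) {
    if (start_plus == (t %% 2 == 1)) {
      out <- c(out, rep(1, plus_sizes[i]))
      i <- i + 1
    } else {
      out <- c(out, rep(-1, minus_sizes[j]))
      j <- j + 1
    }
  }
  stopifnot(sum(out > 0) == n1, sum(out < 0) == n2)
  out
}
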