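test_that("Cochran's Q matches hand evaluation and handles degeneracy", {
  x <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  res <- cochran_q(x)
  expect_equal(res$statistic, 3.0)
  expect_equal(res$df, 2)
  deg <- cochran_q(matrix(rep(c(1, 1, 1), 5), ncol = 3, byrow = TRUE))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(cochran_q(matrix(c(0, 2, 1, 1), 2)), "binary")
  expect_error(cochran_q(matrix(1, 2, 1)), "k >= 2")
})

test_that("Cochran's Q at k = 2 equals the uncorrected McNemar statistic", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    m <- matrix(stats::rbinom(2 * n, 1, stats::runif(1, 0.2, 0.8)), ncol = 2)
    q <- cochran_q(m)$statistic
    b <- sum(m[, 1] == 1 & m[, 2] == 0)
    c_ <- sum(m[, 1] == 0 & m[, 2] == 1)
    expected <- if (b + c_ == 0) 0 else (b - c_)^2 / (b + c_)
    expect_lt(abs(q - expected), 1e-10)
  }
})

test_that("exact McNemar doubles the smaller binomial tail", {
  expect_equal(mcnemar_test(c(rep(TRUE, 5), FALSE),
                            c(rep(FALSE, 5), FALSE),
                            method = "exact")$p_value, 0.0625)
  expect_equal(mcnemar_test(logical(4), logical(4))$p_value, 1)
  # symmetry in the discordant counts
  make <- function(b, c_) {
    a <- c(rep(TRUE, b), rep(FALSE, c_))
    list(a = a, b = !a)
  }
  p1 <- mcnemar_test(make(3, 8)$a, make(3, 8)$b, "exact")$p_value
  p2 <- mcnemar_test(make(8, 3)$a, make(8, 3)$b, "exact")$p_value
  expect_equal(p1, p2)
  expect_error(mcnemar_test(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("exact McNemar agrees with binomial enumeration for b + c <= 20", {
  for (b in 0:20) for (c_ in 0:(20 - b)) {
    a_vec <- c(rep(TRUE, b), rep(FALSE, c_))
    b_vec <- c(rep(FALSE, b), rep(TRUE, c_))
    if (b + c_ == 0) { a_vec <- FALSE; b_vec <- FALSE }
    p <- mcnemar_test(a_vec, b_vec, method = "exact")$p_value
    expect_equal(p, mcnemar_enum_oracle(b, c_), tolerance = 1e-12)
  }
})

test_that("McNemar auto switches from exact to corrected chi-square at 25", {
  a <- c(rep(TRUE, 20), rep(FALSE, 5))
  b <- c(rep(FALSE, 20), rep(TRUE, 5))
  expect_match(mcnemar_test(a, b)$method, "cc_chi2")
  expect_match(mcnemar_test(a[1:24], b[1:24])$method, "exact")
  # continuity-corrected form matches base R's implementation
  ours <- mcnemar_test(a, b, method = "cc_chi2")
  base <- stats::mcnemar.test(table(a, b), correct = TRUE)
  expect_equal(ours$statistic, unname(base$statistic))
  expect_equal(ours$p_value, unname(base$p.value))
})

test_that("Pearson chi-square matches the closed form and base R", {
  res <- chisq_2x2(41, 73, 28, 166)
  expect_equal(res$statistic, 19.15, tolerance = 1e-3)
  expect_lt(res$p_value, 0.001)
  base <- stats::chisq.test(matrix(c(41, 73, 28, 166), 2, byrow = TRUE),
                            correct = FALSE)
  expect_equal(res$statistic, unname(base$statistic))
  expect_equal(res$p_value, unname(base$p.value))
  expect_equal(chisq_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chisq_2x2(10, 10, 10, 10)$p_value, 1)
  # invariant under simultaneous row and column swap
  expect_equal(chisq_2x2(166, 28, 73, 41)$statistic, res$statistic)
  expect_error(chisq_2x2(0, 0, 5, 5), "zero margin")
})

test_that("Fisher exact matches enumeration and base R on random tables", {
  expect_equal(fisher_2x2(0, 5, 5, 0)$p_value, 1 / 126, tolerance = 1e-12)
  expect_equal(fisher_2x2(1, 1, 1, 1)$p_value, 1)
  set.seed(9)
  for (i in 1:50) {
    tab <- stats::rpois(4, 4)
    ours <- fisher_2x2(tab[1], tab[2], tab[3], tab[4])$p_value
    expect_equal(ours, fisher_enum_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
    base <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(ours, base, tolerance = 1e-7)
  }
})

test_that("Fisher and chi-square agree in decision on large balanced tables", {
  set.seed(31)
  for (i in 1:25) {
    repeat {
      tab <- stats::rbinom(4, 120, stats::runif(1, 0.4, 0.6)) + 25
      n <- sum(tab)
      expected <- outer(c(tab[1] + tab[2], tab[3] + tab[4]),
                        c(tab[1] + tab[3], tab[2] + tab[4])) / n
      if (n >= 200 && all(expected >= 20)) break
    }
    pf <- fisher_2x2(tab[1], tab[2], tab[3], tab[4])$p_value
    pc <- chisq_2x2(tab[1], tab[2], tab[3], tab[4])$p_value
    expect_equal(pf < 0.05, pc < 0.05)
  }
})

test_that("the low-expected-count rule is strict at 25 percent", {
  # margins (10, 90) x (40, 60): expecteds (4, 6, 36, 54), exactly one
  # cell of four below 5 -> not *more* than 25%
  expect_false(low_expected_rule(matrix(c(4, 6, 36, 54), 2, byrow = TRUE)))
  expect_true(low_expected_rule(matrix(c(3, 4, 20, 20), 2, byrow = TRUE)))
  expect_false(low_expected_rule(matrix(c(41, 73, 28, 166), 2, byrow = TRUE)))
})

test_that("Welch t from summaries matches a raw-data oracle", {
  res <- welch_t_summary(0.82, 1.00, 114, 0.45, 0.67, 194)
  expect_equal(res$statistic, 3.514, tolerance = 1e-3)
  expect_equal(res$df, 173, tolerance = 1)
  expect_lt(res$p_value, 0.001)
  # raw vectors with exactly those moments reproduce the test
  make <- function(m, s, n, seed) {
    set.seed(seed)
    x <- stats::rnorm(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  x <- make(0.82, 1.00, 114, 1); y <- make(0.45, 0.67, 194, 2)
  base <- stats::t.test(x, y)
  expect_equal(res$statistic, unname(base$statistic), tolerance = 1e-9)
  expect_equal(res$df, unname(base$parameter), tolerance = 1e-6)
  expect_equal(res$p_value, base$p.value, tolerance = 1e-9)
  pooled <- welch_t_summary(0.82, 1.00, 114, 0.45, 0.67, 194, var_equal = TRUE)
  base_p <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(base_p$statistic), tolerance = 1e-9)
  # null and antisymmetry
  expect_equal(welch_t_summary(1, 1, 10, 1, 1, 10)$p_value, 1)
  swap <- welch_t_summary(0.45, 0.67, 194, 0.82, 1.00, 114)
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p_value, res$p_value)
  expect_error(welch_t_summary(0, 1, 1, 0, 1, 10), "n >= 2")
  expect_error(welch_t_summary(0, 0, 10, 0, 1, 10), "positive")
})

test_that("single-proportion sample size reproduces the formula", {
  res <- min_sample_size(0.17, 0.05, 0.95)
  expect_equal(res$n_raw, 216.8, tolerance = 1e-3)
  expect_equal(res$n_floor, 216)
  expect_equal(res$n_ceiling, 217)
  expect_equal(min_sample_size(0.5, 0.05, 0.95)$n_raw, 384.1, tolerance = 1e-3)
  # halving the margin quadruples the requirement
  expect_equal(min_sample_size(0.3, 0.025, 0.95)$n_raw,
               4 * min_sample_size(0.3, 0.05, 0.95)$n_raw)
  expect_error(min_sample_size(0, 0.05), "in \\(0, 1\\)")
})

test_that("half-up percentage rounding uses exact integer arithmetic", {
  expect_equal(percent_round(129, 308, 1), 41.9)
  expect_equal(percent_round(41, 114, 0), 36)
  expect_equal(percent_round(1, 3, 1), 33.3)
  expect_equal(percent_round(1, 8, 0), 13)   # 12.5 rounds up
  expect_equal(percent_round(1, 200, 0), 1)  # 0.5 rounds up
  expect_equal(percent_round(17, 308, 1), 5.5)
  expect_error(percent_round(1, 0), "positive")
  expect_error(percent_round(5, 3), "count <= total")
})
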