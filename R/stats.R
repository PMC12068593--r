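test_result <- function(statistic, df, p_value, method) {
  tibble::tibble(statistic = statistic, df = df,
                 p_value = min(max(p_value, 0), 1), method = method)
}

#' Cochran's Q test for k correlated proportions
#'
#' Omnibus test that k binary classifications of the same N subjects
#' (here: referral flags under k criteria) have equal marginal
#' proportions. The statistic is
#' Q = k(k-1) * sum_j (C_j - T/k)^2 / (k*T - sum_i R_i^2)
#' with column totals C_j, row totals R_i and grand total T, referred to
#' a chi-square distribution on k-1 degrees of freedom. When every row
#' is constant the statistic is degenerate and Q = 0, p = 1 is returned.
#'
#' @param responses an N x k matrix or data frame of 0/1 (or logical)
#'   responses; rows are subjects, columns the correlated classifications.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
cochran_q <- function(responses) {
  x <- as.matrix(responses)
  storage.mode(x) <- "numeric"
  if (ncol(x) < 2) stop("need k >= 2 columns")
  if (any(is.na(x)) || !all(x %in% c(0, 1))) stop("responses must be binary (0/1)")
  k <- ncol(x)
  cj <- colSums(x)
  ri <- rowSums(x)
  tt <- sum(cj)
  denom <- k * tt - sum(ri^2)
  if (denom == 0) {
    return(test_result(0, k - 1, 1, "Cochran's Q"))
  }
  q <- k * (k - 1) * sum((cj - tt / k)^2) / denom
  test_result(q, k - 1, stats::pchisq(q, k - 1, lower.tail = FALSE),
              "Cochran's Q")
}

#' McNemar test for two paired binary classifications
#'
#' Tests marginal homogeneity of two correlated binary flags using the
#' discordant counts b (flagged by the first only) and c (flagged by the
#' second only). The exact test doubles the smaller binomial tail of
#' Binomial(b + c, 1/2); the chi-square form applies the continuity
#' correction (|b - c| - 1)^2 / (b + c) on 1 df. `"auto"` uses the exact
#' test when b + c < 25 and the corrected chi-square otherwise. With no
#' discordant pairs p = 1.
#'
#' @param flags_a,flags_b equal-length logical (or 0/1) vectors.
#' @param method `"auto"`, `"exact"` or `"cc_chi2"`.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
mcnemar_test <- function(flags_a, flags_b, method = c("auto", "exact", "cc_chi2")) {
  method <- match.arg(method)
  if (length(flags_a) != length(flags_b)) stop("paired vectors differ in length")
  a <- as.logical(flags_a)
  b <- as.logical(flags_b)
  nb <- sum(a & !b)
  nc <- sum(!a & b)
  nd <- nb + nc
  if (method == "auto") method <- if (nd < 25) "exact" else "cc_chi2"
  if (nd == 0) {
    return(test_result(0, if (method == "exact") NA_real_ else 1, 1,
                       paste0("McNemar (", method, ")")))
  }
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(nb, nc), nd, 0.5))
    test_result(min(nb, nc), NA_real_, p, "McNemar (exact)")
  } else {
    stat <- (abs(nb - nc) - 1)^2 / nd
    test_result(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
                "McNemar (cc_chi2)")
  }
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form chi^2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) on 1 df,
#' without continuity correction by default (set `correct = TRUE` for
#' the Yates-corrected form).
#'
#' @param a,b,c,d cell counts, row-wise: (a, b) first row, (c, d) second.
#' @param correct apply the Yates continuity correction.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (n == 0 || any(margins == 0)) stop("table has a zero margin")
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(margins)
  test_result(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
              if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square")
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Conditional on both margins, the two-sided p-value sums the
#' hypergeometric probabilities of every table whose probability does
#' not exceed that of the observed table (within a relative tolerance of
#' 1e-7, the customary guard against ties lost to floating point).
#'
#' @inheritParams chisq_2x2
#' @return A one-row tibble with `statistic` (the observed table
#'   probability), `df` (`NA`), `p_value`, `method`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  m <- a + b          # first-row margin
  n2 <- c + d
  k <- a + c          # first-column margin
  lo <- max(0, k - n2)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result(p_obs, NA_real_, p, "Fisher exact (two-sided)")
}

#' Should Fisher's exact test replace the chi-square?
#'
#' Implements the common reporting rule: use the exact test when
#' strictly more than 25\% of the expected cell counts (row total x
#' column total / N) fall below 5.
#'
#' @param counts a matrix (or 2x2-coercible vector, row-wise) of
#'   nonnegative observed counts.
#' @return `TRUE` if the exact test is indicated.
#' @export
low_expected_rule <- function(counts) {
  x <- if (is.matrix(counts)) counts else matrix(counts, nrow = 2, byrow = TRUE)
  if (any(x < 0)) stop("counts must be nonnegative")
  n <- sum(x)
  if (n == 0) stop("empty table")
  expected <- outer(rowSums(x), colSums(x)) / n
  mean(expected < 5) > 0.25
}

#' Two-sample t test from summary statistics
#'
#' Welch's t test (default) or the pooled-variance form, computed from
#' group means, standard deviations and sizes, as needed when comparing
#' published group summaries. Degrees of freedom for the Welch form use
#' the Welch-Satterthwaite approximation.
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @param var_equal use the pooled-variance form.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "t test (pooled)"
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch t test"
  }
  t <- (m1 - m2) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), method)
}

#' Minimum sample size for a single proportion
#'
#' The standard formula n = z^2 p (1 - p) / e^2 with z the two-sided
#' normal quantile for the given confidence level. Because published
#' reports phrase the result as "at least n", the raw value is returned
#' together with both its floor and ceiling.
#'
#' @param p anticipated proportion in (0, 1).
#' @param e margin of error (> 0).
#' @param conf confidence level in (0, 1).
#' @return A one-row tibble with `n_raw`, `n_floor`, `n_ceiling`.
#' @export
min_sample_size <- function(p, e, conf = 0.95) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (e <= 0) stop("margin of error must be positive")
  if (conf <= 0 || conf >= 1) stop("confidence level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n_raw <- z^2 * p * (1 - p) / e^2
  tibble::tibble(n_raw = n_raw, n_floor = floor(n_raw), n_ceiling = ceiling(n_raw))
}

#' Percentage of a count, rounded half-up
#'
#' Computes 100 * count / total and rounds half-up to the requested
#' number of decimals using exact integer arithmetic, so boundary cases
#' (x.5 at the last digit) always round away from zero, matching how
#' screening tables print rates.
#'
#' @param count,total nonnegative counts with `count <= total`,
#'   `total > 0`. Vectorised.
#' @param decimals decimal places.
#' @return Numeric vector of rounded percentages.
#' @export
percent_round <- function(count, total, decimals = 0) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0) || any(count > total)) stop("need 0 <= count <= total")
  scale <- 10^decimals
  num <- count * 100 * scale
  whole <- num %/% total
  rem <- num %% total
  (whole + as.integer(2 * rem >= total)) / scale
}
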