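#' Compare referral and category rates across criteria
#'
#' Runs the full paired-proportion comparison on one cohort: classifies
#' every child under every criterion, tabulates counts and percentages,
#' tests each flag column's equality across criteria with Cochran's Q,
#' and performs pairwise McNemar post-hoc tests (optionally
#' Bonferroni-adjusted). Deterministic and invariant to the row order of
#' the input.
#'
#' @param cohort a validated cohort tibble.
#' @param criteria a criteria tibble.
#' @param convention a [metric_convention()].
#' @param mcnemar_method method passed to [mcnemar_test()].
#' @param bonferroni also report Bonferroni-adjusted pairwise p-values.
#' @param decimals decimal places for rate percentages.
#' @return A list of class `arf_comparison` with elements `rates`
#'   (tabulated counts/percentages), `cochran` (one test per flag
#'   column), `pairwise` (long McNemar matrix: category, criterion_a,
#'   criterion_b, statistic, p_value, method, and `p_adjusted` when
#'   requested) and `flags` (the long flags tibble).
#' @export
run_criteria_comparison <- function(cohort, criteria = builtin_criteria(),
                                    convention = metric_convention(),
                                    mcnemar_method = "auto",
                                    bonferroni = FALSE,
                                    decimals = 1) {
  cohort <- dplyr::arrange(cohort, .data$child_id)
  flags <- classify_cohort(cohort, criteria, convention)
  rates <- tabulate_rates(flags, decimals = decimals)
  crit_names <- unique(criteria$criterion)
  wide <- function(category) {
    m <- tidyr::pivot_wider(
      dplyr::select(flags, "child_id", "criterion", dplyr::all_of(category)),
      names_from = "criterion", values_from = dplyr::all_of(category))
    as.matrix(dplyr::select(m, dplyr::all_of(crit_names))) * 1
  }
  test_cats <- setdiff(flag_categories, "unreadable")
  cochran <- purrr::map_dfr(test_cats, function(cat) {
    dplyr::mutate(cochran_q(wide(cat)), category = cat, .before = 1)
  })
  pairs <- utils::combn(crit_names, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(test_cats, function(cat) {
    m <- wide(cat)
    purrr::map_dfr(pairs, function(pr) {
      res <- mcnemar_test(m[, pr[1]], m[, pr[2]], method = mcnemar_method)
      dplyr::mutate(res, category = cat, criterion_a = pr[1],
                    criterion_b = pr[2], .before = 1)
    })
  })
  if (bonferroni) {
    pairwise <- pairwise |>
      dplyr::group_by(.data$category) |>
      dplyr::mutate(p_adjusted = pmin(1, .data$p_value * dplyr::n())) |>
      dplyr::ungroup()
  }
  structure(list(rates = rates, cochran = cochran, pairwise = pairwise,
                 flags = flags, alpha = 0.05),
            class = "arf_comparison")
}

#' Stratify one criterion's results by school type
#'
#' Tabulates referral, spectacle wear and the four categories per school
#' stratum under a single criterion, tests the 2x2 referral-by-school
#' table with the Pearson chi-square or Fisher's exact test (chosen by
#' [low_expected_rule()]), and compares the strata's child-level
#' spherical equivalents with a Welch t test on the raw values.
#'
#' @param cohort a validated cohort tibble with both school strata.
#' @param criteria a criteria tibble.
#' @param criterion the criterion to stratify.
#' @param convention a [metric_convention()].
#' @return A list of class `arf_stratified` with `by_school` (counts and
#'   half-up percentages per stratum), `referral_test`, `se_test`,
#'   `spectacles_among_referred` (count, n, percent) and `moments`.
#' @export
run_school_stratification <- function(cohort, criteria = builtin_criteria(),
                                      criterion = "aapos2021",
                                      convention = metric_convention()) {
  schools <- unique(cohort$school_type)
  if (!setequal(schools, c("public", "private"))) {
    stop("cohort must contain both public and private strata")
  }
  crit <- criteria[criteria$criterion == criterion, ]
  if (nrow(crit) == 0) stop("unknown criterion: ", criterion)
  flags <- classify_cohort(cohort, crit, convention)
  joined <- dplyr::left_join(
    flags, dplyr::select(cohort, "child_id", "school_type",
                         "wears_spectacles"), by = "child_id")
  by_school <- joined |>
    dplyr::group_by(school_type = factor(.data$school_type,
                                         c("public", "private"))) |>
    dplyr::summarise(
      n = dplyr::n(),
      referred = sum(.data$referred),
      spectacles = sum(.data$wears_spectacles),
      hyperopia = sum(.data$hyperopia),
      myopia = sum(.data$myopia),
      astigmatism = sum(.data$astigmatism),
      anisometropia = sum(.data$anisometropia),
      .groups = "drop") |>
    dplyr::mutate(
      referred_pct = percent_round(.data$referred, .data$n, 0),
      spectacles_pct = percent_round(.data$spectacles, .data$n, 0))
  tab <- c(by_school$referred[1], by_school$n[1] - by_school$referred[1],
           by_school$referred[2], by_school$n[2] - by_school$referred[2])
  referral_test <- if (low_expected_rule(tab)) {
    fisher_2x2(tab[1], tab[2], tab[3], tab[4])
  } else {
    chisq_2x2(tab[1], tab[2], tab[3], tab[4])
  }
  est <- estimate_parameters(cohort, criteria, criterion = NULL,
                             convention = convention)
  mom <- est$moments
  pub <- mom[mom$stratum == "public", ]
  priv <- mom[mom$stratum == "private", ]
  se_test <- welch_t_summary(pub$se_mean, pub$se_sd, pub$n_usable,
                             priv$se_mean, priv$se_sd, priv$n_usable)
  ref_rows <- joined[joined$referred, ]
  spectacles_among_referred <- tibble::tibble(
    count = sum(ref_rows$wears_spectacles),
    n = nrow(ref_rows),
    percent = percent_round(sum(ref_rows$wears_spectacles), nrow(ref_rows), 1))
  structure(list(criterion = criterion, by_school = by_school,
                 referral_test = referral_test, se_test = se_test,
                 spectacles_among_referred = spectacles_among_referred,
                 moments = mom),
            class = "arf_stratified")
}

#' @export
print.arf_comparison <- function(x, ...) {
  cat("Referral-criteria comparison\n")
  ref <- dplyr::filter(x$rates, .data$category == "referred")
  for (i in seq_len(nrow(ref))) {
    cat(sprintf("  %-16s %3d/%d referred (%s%%)\n", ref$criterion[i],
                ref$count[i], ref$n[i], format(ref$percent[i])))
  }
  q <- dplyr::filter(x$cochran, .data$category == "referred")
  cat(sprintf("  Cochran's Q (referral): Q = %.2f, df = %d, p = %.3g\n",
              q$statistic, q$df, q$p_value))
  invisible(x)
}

#' @export
print.arf_stratified <- function(x, ...) {
  cat(sprintf("School stratification under %s\n", x$criterion))
  b <- x$by_school
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-8s %3d children, %3d referred (%s%%)\n",
                b$school_type[i], b$n[i], b$referred[i],
                format(b$referred_pct[i])))
  }
  cat(sprintf("  referral test: %s, p = %.3g\n", x$referral_test$method,
              x$referral_test$p_value))
  cat(sprintf("  SE comparison: t = %.2f, df = %.0f, p = %.3g\n",
              x$se_test$statistic, x$se_test$df, x$se_test$p_value))
  cat(sprintf("  spectacles among referred: %d/%d (%s%%)\n",
              x$spectacles_among_referred$count,
              x$spectacles_among_referred$n,
              format(x$spectacles_among_referred$percent)))
  invisible(x)
}

#' Tidy the tests of a criteria comparison
#'
#' @param x an `arf_comparison` object.
#' @param ... unused.
#' @return A tibble of the Cochran's Q tests, one row per flag column.
#' @export
tidy.arf_comparison <- function(x, ...) x$cochran

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-line summary of a criteria comparison
#'
#' @param x an `arf_comparison` object.
#' @param ... unused.
#' @return A one-row tibble: number of children, criteria, referral
#'   range, and the omnibus referral p-value.
#' @export
glance.arf_comparison <- function(x, ...) {
  ref <- dplyr::filter(x$rates, .data$category == "referred")
  q <- dplyr::filter(x$cochran, .data$category == "referred")
  tibble::tibble(
    n_children = ref$n[1],
    n_criteria = nrow(ref),
    min_referral_pct = min(ref$percent),
    max_referral_pct = max(ref$percent),
    cochran_q = q$statistic,
    p_value = q$p_value
  )
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot referral and category rates by criterion
#'
#' @param object an `arf_comparison` object.
#' @param ... unused.
#' @return A ggplot: one bar per criterion and flag column.
#' @export
autoplot.arf_comparison <- function(object, ...) {
  dat <- dplyr::filter(object$rates, .data$category != "unreadable")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$criterion, y = .data$percent, fill = .data$criterion)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% of screened children") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot referral rates by school stratum
#'
#' @param object an `arf_stratified` object.
#' @param ... unused.
#' @return A ggplot of per-school referral percentages.
#' @export
autoplot.arf_stratified <- function(object, ...) {
  ggplot2::ggplot(object$by_school, ggplot2::aes(
    x = .data$school_type, y = .data$referred_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% referred",
                  title = paste("Referral by school type,", object$criterion)) +
    ggplot2::theme_minimal()
}

#' Serialize a comparison or stratified report to JSON
#'
#' Writes all counts, percentages and test results of a report object;
#' percentages in the output are re-derivable from the serialized counts
#' via [percent_round()].
#'
#' @param report an `arf_comparison` or `arf_stratified` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- unclass(report)
  payload$flags <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
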