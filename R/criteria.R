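#' Built-in referral criteria sets
#'
#' The six published criteria sets compared in this package, as a tidy
#' table of age-banded thresholds: the AAPOS 2021 age-based examination
#' failure levels and the Arthur examination failure criteria (both used
#' as instrument referral criteria), plus four instrument referral
#' criteria -- Arnold medium, Arnold specific, Matta & Silbert, and the
#' Alaska Blind Child Discovery project. Criteria published without age
#' bands repeat the same thresholds in both bands.
#'
#' Thresholds are in diopters: a child fails a category when the
#' configured metric is `>= hyperopia_ge`, `<= myopia_le`,
#' `>= astigmatism_ge` (either eye's |cylinder|), or `>= anisometropia_ge`.
#'
#' @return A tibble with one row per criterion and age band
#'   (`"under4"` / `"ge4"`): columns `criterion`, `label`, `band`,
#'   `hyperopia_ge`, `myopia_le`, `astigmatism_ge`, `anisometropia_ge`.
#' @export
builtin_criteria <- function() {
  spec <- list(
    list("aapos2021", "AAPOS 2021",
         under4 = c(4.00, -3.00, 3.00, 1.25), ge4 = c(4.00, -2.00, 1.75, 1.25)),
    list("arthur", "Arthur",
         under4 = c(3.50, -3.00, 1.25, 1.00), ge4 = c(3.50, -3.00, 1.25, 1.00)),
    list("arnold_medium", "Arnold Medium",
         under4 = c(3.00, -3.50, 3.50, 1.75), ge4 = c(3.00, -2.50, 2.50, 1.75)),
    list("arnold_specific", "Arnold Specific",
         under4 = c(3.50, -3.50, 3.75, 1.75), ge4 = c(3.50, -2.50, 2.75, 1.75)),
    list("matta_silbert", "Matta & Silbert",
         under4 = c(1.25, -1.00, 1.00, 1.25), ge4 = c(1.25, -1.00, 1.00, 1.25)),
    list("abcd", "Alaska Blind Child Discovery",
         under4 = c(2.50, -2.25, 2.25, 1.00), ge4 = c(2.50, -2.25, 2.25, 1.00))
  )
  purrr::map_dfr(spec, function(s) {
    purrr::map_dfr(c("under4", "ge4"), function(band) {
      v <- s[[band]]
      tibble::tibble(
        criterion = s[[1]], label = s[[2]], band = band,
        hyperopia_ge = v[1], myopia_le = v[2],
        astigmatism_ge = v[3], anisometropia_ge = v[4]
      )
    })
  })
}

#' Validate a criteria table
#'
#' @param criteria a criteria tibble as returned by [builtin_criteria()].
#' @return The criteria tibble, invisibly.
#' @export
validate_criteria <- function(criteria) {
  needed <- c("criterion", "band", "hyperopia_ge", "myopia_le",
              "astigmatism_ge", "anisometropia_ge")
  missing_cols <- setdiff(needed, names(criteria))
  if (length(missing_cols) > 0) {
    stop("criteria table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  counts <- dplyr::count(criteria, .data$criterion)
  bad <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(criteria, .data$criterion),
                     ok = setequal(.data$band, c("under4", "ge4")),
                     .groups = "drop"), !.data$ok)
  if (nrow(bad) > 0 || any(counts$n != 2)) {
    stop("each criterion needs exactly one under4 and one ge4 row")
  }
  with(criteria, {
    if (any(hyperopia_ge <= 0) || any(astigmatism_ge <= 0) ||
        any(anisometropia_ge <= 0) || any(myopia_le >= 0)) {
      stop("thresholds must satisfy hyperopia_ge > 0, myopia_le < 0, ",
           "astigmatism_ge > 0, anisometropia_ge > 0")
    }
  })
  invisible(criteria)
}

#' Load / save criteria as YAML
#'
#' The YAML layout is a list of entries
#' `{name, label, bands: {under4: {...}, ge4: {...}}}`, with the four
#' threshold fields per band. Values survive a save/load round trip
#' bit-exactly.
#'
#' @param path a YAML file path.
#' @return For `read_criteria_yaml`, a criteria tibble.
#' @export
read_criteria_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw, function(s) {
    purrr::map_dfr(c("under4", "ge4"), function(band) {
      v <- s$bands[[band]]
      tibble::tibble(
        criterion = s$name, label = s$label %||% s$name, band = band,
        hyperopia_ge = v$hyperopia_ge, myopia_le = v$myopia_le,
        astigmatism_ge = v$astigmatism_ge, anisometropia_ge = v$anisometropia_ge
      )
    })
  })
  validate_criteria(out)
  out
}

#' @param criteria a criteria tibble.
#' @rdname read_criteria_yaml
#' @export
write_criteria_yaml <- function(criteria, path) {
  validate_criteria(criteria)
  entries <- lapply(unique(criteria$criterion), function(cr) {
    rows <- criteria[criteria$criterion == cr, ]
    bands <- lapply(c("under4", "ge4"), function(b) {
      r <- rows[rows$band == b, ]
      list(hyperopia_ge = r$hyperopia_ge, myopia_le = r$myopia_le,
           astigmatism_ge = r$astigmatism_ge,
           anisometropia_ge = r$anisometropia_ge)
    })
    names(bands) <- c("under4", "ge4")
    list(name = cr, label = rows$label[1] %||% cr, bands = bands)
  })
  yaml::write_yaml(entries, path, precision = 15)
  invisible(path)
}

#' Classify every child under every criterion
#'
#' Applies each criterion's age-band thresholds to each child's
#' photorefraction metrics. A category flag is raised when the worse
#' eye's configured metric meets the threshold; an eye displaying the
#' HYP code flags hyperopia and MYO flags myopia under every criterion;
#' a child with an unreadable eye and no flaggable numeric finding is
#' marked `unreadable`. A child is `referred` when any category flag or
#' the unreadable flag is raised.
#'
#' @param cohort a validated cohort tibble (see [read_cohort()]).
#' @param criteria a criteria tibble; defaults to [builtin_criteria()].
#' @param convention a [metric_convention()].
#' @return A long tibble, one row per child x criterion, with logical
#'   columns `hyperopia`, `myopia`, `astigmatism`, `anisometropia`,
#'   `unreadable`, `referred`. Row order follows the input cohort order
#'   within each criterion (input criterion order).
#' @export
classify_cohort <- function(cohort, criteria = builtin_criteria(),
                            convention = metric_convention()) {
  if (nrow(cohort) == 0) stop("empty cohort")
  validate_criteria(criteria)
  thr_max <- max(criteria$hyperopia_ge)
  thr_min <- min(criteria$myopia_le)
  if (convention$hyp_code_surrogate <= thr_max ||
      convention$myo_code_surrogate >= thr_min) {
    stop("code surrogates must dominate every registered threshold")
  }
  if (!"age_band" %in% names(cohort)) {
    cohort <- dplyr::mutate(cohort,
                            age_band = ifelse(.data$age_years >= 4, "ge4", "under4"))
  }
  m <- add_refraction_metrics(cohort, convention)
  m$..order <- seq_len(nrow(m))
  crit_names <- unique(criteria$criterion)
  long <- dplyr::inner_join(
    dplyr::select(m, dplyr::all_of(c("child_id", "age_band", "od_status",
                                     "os_status", "hyp_metric", "myo_metric",
                                     "max_cyl", "aniso", "..order"))),
    criteria, by = c("age_band" = "band"), relationship = "many-to-many"
  )
  has_hyp_code <- long$od_status == "hyp" | long$os_status == "hyp"
  has_myo_code <- long$od_status == "myo" | long$os_status == "myo"
  has_unread <- long$od_status == "unreadable" | long$os_status == "unreadable"
  ge <- function(x, t) !is.na(x) & x >= t
  le <- function(x, t) !is.na(x) & x <= t
  out <- tibble::tibble(
    child_id = long$child_id,
    criterion = long$criterion,
    age_band = long$age_band,
    hyperopia = ge(long$hyp_metric, long$hyperopia_ge) | has_hyp_code,
    myopia = le(long$myo_metric, long$myopia_le) | has_myo_code,
    astigmatism = ge(long$max_cyl, long$astigmatism_ge),
    anisometropia = ge(long$aniso, long$anisometropia_ge),
    ..order = long$..order
  )
  out$unreadable <- has_unread & !(out$hyperopia | out$myopia |
                                     out$astigmatism | out$anisometropia)
  out$referred <- out$hyperopia | out$myopia | out$astigmatism |
    out$anisometropia | out$unreadable
  out |>
    dplyr::mutate(criterion = factor(.data$criterion, levels = crit_names)) |>
    dplyr::arrange(.data$criterion, .data$..order) |>
    dplyr::mutate(criterion = as.character(.data$criterion)) |>
    dplyr::select(-"..order")
}

flag_categories <- c("referred", "hyperopia", "myopia", "astigmatism",
                     "anisometropia", "unreadable")

#' Tabulate referral and category rates per criterion
#'
#' Counts children with each flag raised under each criterion and
#' attaches percentages of all screened children, rounded half-up via
#' [percent_round()].
#'
#' @param flags a long flags tibble from [classify_cohort()].
#' @param decimals decimal places for the percentage.
#' @return A tibble with columns `criterion`, `category`, `count`, `n`,
#'   `percent`.
#' @export
tabulate_rates <- function(flags, decimals = 1) {
  if (nrow(flags) == 0) stop("empty flags table")
  n_children <- dplyr::n_distinct(flags$child_id)
  crit_names <- unique(flags$criterion)
  flags |>
    tidyr::pivot_longer(dplyr::all_of(flag_categories),
                        names_to = "category", values_to = "flag") |>
    dplyr::group_by(.data$criterion, .data$category) |>
    dplyr::summarise(count = sum(.data$flag), .groups = "drop") |>
    dplyr::mutate(
      n = n_children,
      percent = percent_round(.data$count, .data$n, decimals),
      criterion = factor(.data$criterion, levels = crit_names),
      category = factor(.data$category, levels = flag_categories)
    ) |>
    dplyr::arrange(.data$criterion, .data$category) |>
    dplyr::mutate(criterion = as.character(.data$criterion),
                  category = as.character(.data$category))
}
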