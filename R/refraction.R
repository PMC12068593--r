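#' Convert a sphere/cylinder/axis refraction to minus-cylinder form
#'
#' Photorefraction results can be written with either a plus or a minus
#' cylinder. All threshold logic in this package operates on the
#' minus-cylinder form, in which the sphere is the most-plus meridional
#' power. Transposition adds the cylinder to the sphere, negates the
#' cylinder, and rotates the axis by 90 degrees; the pair of meridional
#' powers is unchanged.
#'
#' @param sphere,cylinder numeric vectors, diopters.
#' @param axis numeric vector, degrees in (0, 180]. May be `NA` where the
#'   cylinder is zero.
#' @return A tibble with columns `sphere`, `cylinder` (<= 0) and `axis`.
#' @examples
#' normalize_to_minus_cylinder(+1, +2, 90) # sphere 3, cylinder -2, axis 180
#' @export
normalize_to_minus_cylinder <- function(sphere, cylinder, axis) {
  n <- max(length(sphere), length(cylinder), length(axis))
  sphere <- rep_len(as.numeric(sphere), n)
  cylinder <- rep_len(as.numeric(cylinder), n)
  axis <- rep_len(as.numeric(axis), n)
  bad_axis <- !is.na(axis) & (axis <= 0 | axis > 180)
  if (any(bad_axis)) {
    stop("axis must lie in (0, 180]; offending value(s): ",
         paste(axis[bad_axis], collapse = ", "))
  }
  missing_axis <- is.na(axis) & !is.na(cylinder) & cylinder != 0
  if (any(missing_axis)) {
    stop("axis is required when cylinder is nonzero")
  }
  flip <- !is.na(cylinder) & cylinder > 0
  new_axis <- axis
  new_axis[flip] <- ifelse(axis[flip] + 90 > 180, axis[flip] - 90, axis[flip] + 90)
  tibble::tibble(
    sphere = ifelse(flip, sphere + cylinder, sphere),
    cylinder = ifelse(flip, -cylinder, cylinder),
    axis = new_axis
  )
}

#' Spherical equivalent of a refraction
#'
#' The single-number summary sphere + cylinder/2, invariant under
#' plus/minus-cylinder transposition.
#'
#' @param sphere,cylinder numeric vectors, diopters.
#' @return Numeric vector of spherical equivalents in diopters.
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  sphere + cylinder / 2
}

#' Meridional powers of a refraction
#'
#' In minus-cylinder form the sphere is the power of the most-plus
#' meridian and sphere + cylinder that of the most-minus meridian.
#' Input in either cylinder convention is accepted.
#'
#' @param sphere,cylinder numeric vectors, diopters.
#' @return A tibble with columns `most_plus` and `most_minus`
#'   (`most_plus >= most_minus`).
#' @export
meridional_powers <- function(sphere, cylinder) {
  s <- ifelse(!is.na(cylinder) & cylinder > 0, sphere + cylinder, sphere)
  c_ <- -abs(cylinder)
  tibble::tibble(most_plus = s, most_minus = s + c_)
}

#' Metric convention for threshold classification
#'
#' Published referral criteria state thresholds per refractive-error
#' category but not always which component of the refraction they are
#' applied to. This object fixes those choices. Defaults: hyperopia is
#' judged on the most-plus meridian (the sphere in minus-cylinder form),
#' myopia on the spherical equivalent, and anisometropia on the absolute
#' interocular spherical-equivalent difference.
#'
#' Device status codes carry no numeric reading; the surrogate values are
#' used only where a numeric stand-in is unavoidable (e.g. summary plots).
#' Classification treats codes categorically, so the surrogates must
#' dominate every registered threshold.
#'
#' @param hyperopia_metric `"sphere_most_plus"` or `"se"`.
#' @param myopia_metric `"se"` or `"most_minus_meridian"`.
#' @param aniso_metric `"se_diff"`, `"sphere_diff"` or `"max_meridian_diff"`.
#' @param hyp_code_surrogate,myo_code_surrogate diopter stand-ins for the
#'   HYP (> +5.00 D) and MYO device codes.
#' @return A list of class `arf_convention`.
#' @export
metric_convention <- function(hyperopia_metric = c("sphere_most_plus", "se"),
                              myopia_metric = c("se", "most_minus_meridian"),
                              aniso_metric = c("se_diff", "sphere_diff",
                                               "max_meridian_diff"),
                              hyp_code_surrogate = 5.5,
                              myo_code_surrogate = -7.5) {
  out <- list(
    hyperopia_metric = match.arg(hyperopia_metric),
    myopia_metric = match.arg(myopia_metric),
    aniso_metric = match.arg(aniso_metric),
    hyp_code_surrogate = hyp_code_surrogate,
    myo_code_surrogate = myo_code_surrogate
  )
  class(out) <- "arf_convention"
  out
}

# Per-eye metric columns for one eye of a cohort, in minus-cylinder form.
# Returns tibble(se, most_plus, most_minus, cyl_mag) with NA for coded eyes.
eye_metrics <- function(status, sphere, cylinder, axis) {
  num <- status == "numeric"
  sph <- ifelse(num, sphere, NA_real_)
  cyl <- ifelse(num, cylinder, NA_real_)
  mp <- ifelse(!is.na(cyl) & cyl > 0, sph + cyl, sph)
  cylm <- abs(cyl)
  tibble::tibble(
    se = sph + ifelse(is.na(cyl), 0, cyl) / 2,
    most_plus = mp,
    most_minus = mp - ifelse(is.na(cylm), 0, cylm),
    cyl_mag = cylm
  )
}

#' Derive per-child refraction metrics for a cohort
#'
#' Adds the per-child quantities the referral criteria are tested
#' against: the worse-eye hyperopia and myopia metrics, the larger
#' cylinder magnitude, and the interocular anisometropia value under the
#' given convention. Children with a coded (HYP/MYO/UNREADABLE) eye get
#' `NA` for metrics that need that eye's numeric reading.
#'
#' @param cohort a cohort tibble (see [read_cohort()]).
#' @param convention a [metric_convention()].
#' @return The cohort with columns `hyp_metric`, `myo_metric`, `max_cyl`,
#'   `aniso`, `od_se`, `os_se` appended.
#' @export
add_refraction_metrics <- function(cohort, convention = metric_convention()) {
  od <- eye_metrics(cohort$od_status, cohort$od_sphere, cohort$od_cylinder,
                    cohort$od_axis)
  os <- eye_metrics(cohort$os_status, cohort$os_sphere, cohort$os_cylinder,
                    cohort$os_axis)
  hyp <- switch(convention$hyperopia_metric,
    sphere_most_plus = pmax(od$most_plus, os$most_plus, na.rm = TRUE),
    se = pmax(od$se, os$se, na.rm = TRUE)
  )
  myo <- switch(convention$myopia_metric,
    se = pmin(od$se, os$se, na.rm = TRUE),
    most_minus_meridian = pmin(od$most_minus, os$most_minus, na.rm = TRUE)
  )
  # pmax/pmin with na.rm = TRUE yield +-Inf when both eyes are coded
  hyp[is.infinite(hyp)] <- NA_real_
  myo[is.infinite(myo)] <- NA_real_
  both_numeric <- cohort$od_status == "numeric" & cohort$os_status == "numeric"
  aniso <- switch(convention$aniso_metric,
    se_diff = abs(od$se - os$se),
    sphere_diff = abs(od$most_plus - os$most_plus),
    max_meridian_diff = pmax(abs(od$most_plus - os$most_plus),
                             abs(od$most_minus - os$most_minus))
  )
  aniso[!both_numeric] <- NA_real_
  dplyr::mutate(cohort,
    od_se = od$se, os_se = os$se,
    hyp_metric = hyp, myo_metric = myo,
    max_cyl = pmax(od$cyl_mag, os$cyl_mag, na.rm = TRUE),
    aniso = aniso
  ) |>
    dplyr::mutate(max_cyl = ifelse(is.infinite(.data$max_cyl) |
                                     (.data$od_status != "numeric" &
                                        .data$os_status != "numeric"),
                                   NA_real_, .data$max_cyl))
}

#' Interocular anisometropia of one pair of eyes
#'
#' Absolute interocular difference of the configured per-eye quantity
#' (spherical equivalent by default). Returns `NA` (undefined, distinct
#' from zero) when either eye carries a device status code instead of a
#' numeric reading.
#'
#' @param od,os lists or one-row data frames with elements `status`,
#'   `sphere`, `cylinder`, `axis`.
#' @param convention a [metric_convention()].
#' @return A length-1 numeric, `NA` if undefined.
#' @export
anisometropia_value <- function(od, os, convention = metric_convention()) {
  mini <- tibble::tibble(
    child_id = "x", age_years = 5, school_type = "public", grade = "kg2",
    sex = "f", wears_spectacles = FALSE,
    od_status = od$status, od_sphere = od$sphere %||% NA_real_,
    od_cylinder = od$cylinder %||% NA_real_, od_axis = od$axis %||% NA_real_,
    os_status = os$status, os_sphere = os$sphere %||% NA_real_,
    os_cylinder = os$cylinder %||% NA_real_, os_axis = os$axis %||% NA_real_
  )
  add_refraction_metrics(mini, convention)$aniso
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cohort_columns <- c(
  "child_id", "age_years", "school_type", "grade", "sex",
  "wears_spectacles", "od_status", "od_sphere", "od_cylinder", "od_axis",
  "os_status", "os_sphere", "os_cylinder", "os_axis"
)

#' Validate a cohort table
#'
#' Checks the schema and invariants of a per-child screening table:
#' required columns, enum levels, the presence of numeric fields exactly
#' when an eye's status is `numeric`, axis in (0, 180] (required whenever
#' the cylinder is nonzero -- a missing axis is rejected, not defaulted),
#' readings within the device range, ages in [2, 8] years, and unique
#' child ids. All problems are reported together, each naming the row and
#' field.
#'
#' @param cohort a data frame to validate.
#' @param device_range length-2 numeric, allowed sphere range in diopters.
#' @param max_cylinder maximum |cylinder| in diopters.
#' @return The validated cohort, invisibly coerced to a tibble with a
#'   derived `age_band` column (`"under4"` / `"ge4"`, boundary 4.0 years).
#' @export
validate_cohort <- function(cohort, device_range = c(-7, 5), max_cylinder = 7) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  problems <- character()
  note <- function(row, field, msg) {
    problems <<- c(problems, sprintf("row %d, field %s: %s", row, field, msg))
  }
  cohort$school_type <- tolower(as.character(cohort$school_type))
  cohort$grade <- tolower(as.character(cohort$grade))
  cohort$sex <- tolower(as.character(cohort$sex))
  for (eye in c("od", "os")) {
    st <- paste0(eye, "_status")
    cohort[[st]] <- tolower(as.character(cohort[[st]]))
  }
  if (is.numeric(cohort$wears_spectacles)) {
    cohort$wears_spectacles <- cohort$wears_spectacles != 0
  }
  dup <- duplicated(cohort$child_id)
  for (i in which(dup)) note(i, "child_id", "duplicate id")
  for (i in seq_len(nrow(cohort))) {
    age <- cohort$age_years[i]
    if (is.na(age) || age < 2 || age > 8) note(i, "age_years", "must be in [2, 8]")
    if (!cohort$school_type[i] %in% c("public", "private"))
      note(i, "school_type", "must be public or private")
    if (!cohort$grade[i] %in% c("nursery", "kg1", "kg2", "kg3", "grade1"))
      note(i, "grade", "unknown grade")
    if (!cohort$sex[i] %in% c("f", "m")) note(i, "sex", "must be f or m")
    for (eye in c("od", "os")) {
      st <- cohort[[paste0(eye, "_status")]][i]
      sph <- cohort[[paste0(eye, "_sphere")]][i]
      cyl <- cohort[[paste0(eye, "_cylinder")]][i]
      ax <- cohort[[paste0(eye, "_axis")]][i]
      if (!st %in% c("numeric", "hyp", "myo", "unreadable")) {
        note(i, paste0(eye, "_status"), "unknown status code")
        next
      }
      if (st == "numeric") {
        if (is.na(sph)) note(i, paste0(eye, "_sphere"), "required for numeric status")
        if (is.na(cyl)) note(i, paste0(eye, "_cylinder"), "required for numeric status")
        if (!is.na(sph) && (sph < device_range[1] || sph > device_range[2]))
          note(i, paste0(eye, "_sphere"),
               sprintf("outside device range [%g, %g]", device_range[1], device_range[2]))
        if (!is.na(cyl) && abs(cyl) > max_cylinder)
          note(i, paste0(eye, "_cylinder"),
               sprintf("|cylinder| exceeds %g", max_cylinder))
        if (!is.na(cyl) && cyl != 0) {
          if (is.na(ax)) {
            note(i, paste0(eye, "_axis"), "required when cylinder is nonzero")
          } else if (ax <= 0 || ax > 180) {
            note(i, paste0(eye, "_axis"), "must be in (0, 180]")
          }
        } else if (!is.na(ax) && (ax <= 0 || ax > 180)) {
          note(i, paste0(eye, "_axis"), "must be in (0, 180]")
        }
      } else {
        if (!is.na(sph) || !is.na(cyl) || !is.na(ax))
          note(i, paste0(eye, "_sphere"),
               "numeric fields must be blank when status is a code")
      }
    }
  }
  if (length(problems) > 0) {
    stop("invalid cohort:\n", paste(" -", problems, collapse = "\n"))
  }
  dplyr::mutate(cohort,
                age_band = ifelse(.data$age_years >= 4, "ge4", "under4"),
                .after = "age_years")
}

#' Read a cohort CSV
#'
#' Reads the standard per-child screening schema (one row per child,
#' columns for demographics and both eyes' readings or status codes) and
#' validates it with [validate_cohort()]. Lines starting with `#` are
#' treated as comments. Status codes are parsed case-insensitively.
#'
#' @param path path to a CSV file.
#' @inheritParams validate_cohort
#' @return A validated cohort tibble with a derived `age_band` column.
#' @export
read_cohort <- function(path, device_range = c(-7, 5), max_cylinder = 7) {
  raw <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      child_id = readr::col_character(),
      age_years = readr::col_double(),
      school_type = readr::col_character(),
      grade = readr::col_character(),
      sex = readr::col_character(),
      wears_spectacles = readr::col_double(),
      od_status = readr::col_character(),
      od_sphere = readr::col_double(),
      od_cylinder = readr::col_double(),
      od_axis = readr::col_double(),
      os_status = readr::col_character(),
      os_sphere = readr::col_double(),
      os_cylinder = readr::col_double(),
      os_axis = readr::col_double()
    )
  )
  validate_cohort(raw, device_range = device_range, max_cylinder = max_cylinder)
}

#' Write a cohort CSV
#'
#' Writes the standard schema (derived columns are dropped) so that a
#' write-then-read round trip reproduces the records exactly.
#'
#' @param cohort a cohort tibble.
#' @param path output path.
#' @param header_comment optional character vector written as `#` comment
#'   lines above the header (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, header_comment = NULL) {
  out <- dplyr::select(cohort, dplyr::all_of(cohort_columns)) |>
    dplyr::mutate(wears_spectacles = as.integer(.data$wears_spectacles))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
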