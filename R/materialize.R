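# Concrete eye readings for a standalone (single-finding) child. Values
# are chosen on the 0.25 D grid where the constraints allow, keeping the
# unaffected quantities clear of every built-in threshold (fellow-eye
# spheres below +1.25 D, spherical equivalents above -1.00 D, cylinders
# below 1.00 D, interocular differences below 1.00 D).
standalone_eyes <- function(category, value) {
  switch(category,
    hyperopia = child_eyes(od = c(value, 0), os = c(value, 0)),
    myopia = child_eyes(od = c(-value, 0), os = c(-value, 0)),
    astigmatism = {
      s <- max(0.25, quarter_ceil(value / 2 - 0.875))
      se <- s - value / 2
      child_eyes(od = c(s, -value), os = c(quarter_ceil(se), 0))
    },
    anisometropia = {
      ve <- min(value, 2) # a larger split would push an eye past a threshold
      child_eyes(od = c(-0.875, 0), os = c(ve - 0.875, 0))
    }
  )
}

blank_child <- function(band, eyes = NULL, status = "numeric") {
  row <- tibble::tibble(
    child_id = NA_character_,
    age_years = if (band == "under4") 3.5 else 5,
    school_type = "public", grade = "kg2", sex = "f",
    wears_spectacles = FALSE,
    od_status = status, od_sphere = NA_real_, od_cylinder = NA_real_,
    od_axis = NA_real_,
    os_status = status, os_sphere = NA_real_, os_cylinder = NA_real_,
    os_axis = NA_real_
  )
  if (status == "numeric") {
    row$od_sphere <- eyes$od_sphere
    row$od_cylinder <- eyes$od_cylinder
    row$od_axis <- if (eyes$od_cylinder != 0) 180 else NA_real_
    row$os_sphere <- eyes$os_sphere
    row$os_cylinder <- eyes$os_cylinder
    row$os_axis <- if (eyes$os_cylinder != 0) 180 else NA_real_
  }
  row
}

# Classify a single archetype child and assert that its flags under every
# criterion are exactly the intended ones; the fixture is an acceptance
# surface, so any drift is a hard error.
check_archetype <- function(row, intended, criteria, convention, what) {
  flags <- classify_cohort(dplyr::mutate(row, child_id = "chk"),
                           criteria, convention)
  for (cat in categories4) {
    got <- flags$criterion[flags[[cat]]]
    want <- intended[[cat]] %||% character()
    if (!setequal(got, want)) {
      stop(sprintf(
        "archetype '%s': %s flagged by {%s}, expected {%s}", what, cat,
        paste(sort(got), collapse = ","), paste(sort(want), collapse = ",")))
    }
  }
  want_unread <- isTRUE(intended$unreadable)
  if (any(flags$unreadable) != want_unread) {
    stop(sprintf("archetype '%s': unexpected unreadable flag", what))
  }
  invisible(TRUE)
}

#' Materialize the reconstructed cohort from an overlap plan
#'
#' Places concrete refraction values for every planned child: merged
#' multi-finding children from the overlap moves, standalone children at
#' the representative value of their allocated region, device-coded
#' (HYP/MYO) and unreadable children, and unremarkable children filling
#' the age-band margins. Every archetype is re-classified on the spot
#' and must flag exactly the intended criteria. Demographics (school,
#' grade, sex, spectacle wear) are then assigned to reproduce the
#' school-stratified margins, and the finished cohort is re-classified
#' as a whole: any per-criterion category-count mismatch against the
#' targets is a hard error, while union (referral) residuals are
#' reported in the reconstruction report.
#'
#' @param plan a plan from [plan_overlaps()].
#' @param targets the targets list the plan was built from.
#' @param criteria,convention the classification setup.
#' @return A list with `cohort` (a validated cohort tibble) and `report`
#'   (category/union/school checks and the move summary).
#' @export
materialize_fixture <- function(plan, targets, criteria = builtin_criteria(),
                                convention = metric_convention()) {
  crits <- unique(criteria$criterion)
  rows <- list()
  add <- function(row) rows[[length(rows) + 1]] <<- row

  # merged children from overlap moves
  if (nrow(plan$moves) > 0) {
    for (i in seq_len(nrow(plan$moves))) {
      mv <- plan$moves[i, ]
      row <- blank_child(mv$band, mv$build[[1]]())
      intended <- list()
      for (s in mv$slots[[1]]) intended[[s$category]] <- s$set
      check_archetype(row, intended, criteria, convention, mv$template)
      for (j in seq_len(mv$count)) add(row)
    }
  }

  # standalone children for the unconsumed part of every region
  for (cat in categories4) {
    alloc <- plan$allocations[[cat]]
    for (i in seq_len(nrow(alloc))) {
      key <- paste0(alloc$band[i], ":", alloc$region[i])
      left <- alloc$count[i] - (plan$consumed[[cat]][[key]] %||% 0L)
      if (left < 0) stop("overlap plan consumed more than region capacity")
      if (left == 0) next
      band <- if (alloc$band[i] == "any") "ge4" else alloc$band[i]
      row <- blank_child(band, standalone_eyes(cat, alloc$value[i]))
      check_archetype(row, stats::setNames(list(alloc$criteria[[i]]), cat),
                      criteria, convention,
                      sprintf("%s region %d (%s)", cat, alloc$region[i], band))
      for (j in seq_len(left)) add(row)
    }
  }

  codes <- targets$codes
  code_row <- function(status, intended) {
    row <- blank_child("ge4", status = status)
    check_archetype(row, intended, criteria, convention, status)
    row
  }
  if (codes$hyp > 0) {
    row <- code_row("hyp", list(hyperopia = crits))
    for (j in seq_len(codes$hyp)) add(row)
  }
  if (codes$myo > 0) {
    row <- code_row("myo", list(myopia = crits))
    for (j in seq_len(codes$myo)) add(row)
  }
  if (codes$unreadable > 0) {
    row <- code_row("unreadable", list(unreadable = TRUE))
    for (j in seq_len(codes$unreadable)) add(row)
  }

  kids <- dplyr::bind_rows(rows)
  kids$age_band <- ifelse(kids$age_years >= 4, "ge4", "under4")
  band_sizes <- targets$cohort$band_sizes
  filler <- blank_child("ge4", child_eyes(od = c(0.5, -0.5), os = c(0.5, -0.5)))
  check_archetype(filler, list(), criteria, convention, "unremarkable")
  for (b in c("under4", "ge4")) {
    used <- sum(kids$age_band == b)
    if (used > band_sizes[[b]]) {
      stop(sprintf("allocation places %d children in band %s but the band holds %d",
                   used, b, band_sizes[[b]]))
    }
    fill <- filler
    fill$age_years <- if (b == "under4") 3.5 else 5
    fill$age_band <- b
    for (j in seq_len(band_sizes[[b]] - used)) kids <- dplyr::bind_rows(kids, fill)
  }
  kids$age_band <- ifelse(kids$age_years >= 4, "ge4", "under4")
  kids$child_id <- sprintf("c%03d", seq_len(nrow(kids)))

  kids <- assign_demographics(kids, targets, criteria, convention)
  cohort <- validate_cohort(dplyr::select(kids, dplyr::all_of(cohort_columns)))

  report <- verify_reconstruction(cohort, plan, targets, criteria, convention)
  list(cohort = cohort, report = report)
}

# Assign school, grade, sex and spectacle wear so the stratified margins
# (referral by school, spectacles among referred, age band by school,
# grade and sex totals) are reproduced. Deterministic in cohort order.
assign_demographics <- function(kids, targets, criteria, convention) {
  strat <- targets$stratify
  crit_rows <- criteria[criteria$criterion == strat$criterion, ]
  if (nrow(crit_rows) == 0) stop("stratify criterion not in criteria table")
  flags <- classify_cohort(kids, crit_rows, convention)
  referred <- flags$referred[match(kids$child_id, flags$child_id)]
  bbs <- targets$cohort$band_by_school
  ref_sch <- strat$referred_by_school
  n_ref_u <- sum(referred & kids$age_band == "under4")
  pub_ref_u <- min(n_ref_u, bbs$public$under4, ref_sch$public)
  quota <- list(
    public = list(ref = c(under4 = pub_ref_u,
                          ge4 = ref_sch$public - pub_ref_u),
                  non = c(under4 = bbs$public$under4 - pub_ref_u,
                          ge4 = bbs$public$ge4 - (ref_sch$public - pub_ref_u)))
  )
  quota$private <- list(
    ref = c(under4 = n_ref_u - pub_ref_u,
            ge4 = sum(referred & kids$age_band == "ge4") -
              quota$public$ref[["ge4"]]),
    non = c(under4 = bbs$private$under4 - (n_ref_u - pub_ref_u),
            ge4 = NA)
  )
  quota$private$non[["ge4"]] <- bbs$private$ge4 - quota$private$ref[["ge4"]]
  if (any(unlist(quota) < 0, na.rm = TRUE)) {
    stop("school margins are infeasible for this cohort")
  }
  school <- character(nrow(kids))
  for (i in seq_len(nrow(kids))) {
    kind <- if (referred[i]) "ref" else "non"
    b <- kids$age_band[i]
    if (quota$public[[kind]][[b]] > 0) {
      school[i] <- "public"
      quota$public[[kind]][[b]] <- quota$public[[kind]][[b]] - 1
    } else {
      school[i] <- "private"
      quota$private[[kind]][[b]] <- quota$private[[kind]][[b]] - 1
    }
  }
  kids$school_type <- school

  spect <- strat$spectacles_referred_by_school
  kids$wears_spectacles <- FALSE
  for (sch in c("public", "private")) {
    idx <- which(kids$school_type == sch & referred)
    take <- spect[[sch]]
    if (take > length(idx)) stop("spectacle margin exceeds referred children")
    kids$wears_spectacles[idx[seq_len(take)]] <- TRUE
  }

  grades <- targets$demographics$grades
  sexes <- targets$demographics$sex
  grade_order <- c("nursery", "kg1", "kg2", "kg3", "grade1")
  for (sch in c("public", "private")) {
    idx <- which(kids$school_type == sch)
    idx <- idx[order(kids$age_band[idx] != "under4")] # younger first
    seq_grades <- rep(grade_order, times = unlist(grades[[sch]])[grade_order])
    if (length(seq_grades) != length(idx)) stop("grade margins do not sum to school size")
    kids$grade[idx] <- seq_grades
    idx2 <- which(kids$school_type == sch)
    n_f <- sexes[[sch]]$f
    if (n_f + sexes[[sch]]$m != length(idx2)) stop("sex margins do not sum to school size")
    kids$sex[idx2] <- rep(c("f", "m"), times = c(n_f, length(idx2) - n_f))
  }
  kids
}

verify_reconstruction <- function(cohort, plan, targets, criteria, convention) {
  cc <- dplyr::bind_rows(lapply(targets$criteria_counts, tibble::as_tibble))
  flags <- classify_cohort(cohort, criteria, convention)
  rates <- tabulate_rates(flags, decimals = 1)
  target_long <- tidyr::pivot_longer(
    cc, dplyr::all_of(c("union", categories4)),
    names_to = "category", values_to = "target") |>
    dplyr::mutate(category = ifelse(.data$category == "union", "referred",
                                    .data$category))
  achieved <- dplyr::select(rates, "criterion", "category", achieved = "count")
  check <- dplyr::left_join(target_long, achieved,
                            by = c("criterion", "category")) |>
    dplyr::mutate(residual = .data$achieved - .data$target)
  cat_bad <- dplyr::filter(check, .data$category != "referred", .data$residual != 0)
  if (nrow(cat_bad) > 0) {
    stop("reconstruction failed to reproduce category counts:\n",
         paste(utils::capture.output(print(cat_bad)), collapse = "\n"))
  }
  # the union count under both accountings of unreadable-only children
  union_excl <- flags |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(excl = sum(.data$referred & !.data$unreadable),
                     .groups = "drop")
  union_check <- dplyr::filter(check, .data$category == "referred") |>
    dplyr::left_join(union_excl, by = "criterion") |>
    dplyr::select("criterion", "target", "achieved", "residual",
                  achieved_excluding_unreadable = "excl")

  strat <- targets$stratify
  sflags <- dplyr::filter(flags, .data$criterion == strat$criterion)
  joined <- dplyr::left_join(
    sflags, dplyr::select(cohort, "child_id", "school_type",
                          "wears_spectacles"), by = "child_id")
  school_check <- joined |>
    dplyr::group_by(.data$school_type) |>
    dplyr::summarise(
      n = dplyr::n(), referred = sum(.data$referred),
      spectacles_referred = sum(.data$referred & .data$wears_spectacles),
      hyperopia = sum(.data$hyperopia), myopia = sum(.data$myopia),
      astigmatism = sum(.data$astigmatism),
      anisometropia = sum(.data$anisometropia), .groups = "drop")
  cat_by_school <- strat$category_by_school
  school_target <- tibble::tibble(
    school_type = c("public", "private"),
    referred_target = c(strat$referred_by_school$public,
                        strat$referred_by_school$private),
    hyperopia_target = c(cat_by_school$hyperopia$public,
                         cat_by_school$hyperopia$private),
    myopia_target = c(cat_by_school$myopia$public, cat_by_school$myopia$private),
    astigmatism_target = c(cat_by_school$astigmatism$public,
                           cat_by_school$astigmatism$private),
    anisometropia_target = c(cat_by_school$anisometropia$public,
                             cat_by_school$anisometropia$private))
  school_check <- dplyr::left_join(school_check, school_target,
                                   by = "school_type")

  moves <- if (nrow(plan$moves) > 0) {
    dplyr::select(plan$moves, "template", "band", "count")
  } else {
    tibble::tibble(template = character(), band = character(),
                   count = integer())
  }
  structure(list(
    category_check = dplyr::filter(check, .data$category != "referred"),
    union_check = union_check,
    school_check = school_check,
    moves = moves,
    feasible = all(union_check$residual == 0)
  ), class = "arf_reconstruction_report")
}

#' Reconstruct the packaged screening cohort from its published margins
#'
#' End-to-end deterministic reconstruction: plans category allocations
#' and overlaps with [plan_overlaps()], then materializes and verifies
#' the cohort with [materialize_fixture()]. Identical targets yield a
#' byte-identical cohort CSV.
#'
#' @param targets a targets list, defaulting to the packaged
#'   [reconstruction_targets()].
#' @param criteria,convention the classification setup.
#' @return A list with `cohort` and `report` (see
#'   [materialize_fixture()]).
#' @export
reconstruct_cohort <- function(targets = reconstruction_targets(),
                               criteria = builtin_criteria(),
                               convention = metric_convention()) {
  plan <- plan_overlaps(criteria, targets)
  materialize_fixture(plan, targets, criteria, convention)
}

#' @export
print.arf_reconstruction_report <- function(x, ...) {
  cat("Cohort reconstruction report\n")
  cat(sprintf("  category counts reproduced exactly: %s\n",
              all(x$category_check$residual == 0)))
  cat(sprintf("  union residuals: %s\n",
              paste(sprintf("%s %+d", x$union_check$criterion,
                            x$union_check$residual), collapse = ", ")))
  cat(sprintf("  overlap moves: %d (children merged: %d)\n",
              nrow(x$moves), sum(x$moves$count)))
  invisible(x)
}
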