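test_that("built-in criteria carry the published thresholds", {
  cr <- builtin_criteria()
  get <- function(c_, b, col) cr[[col]][cr$criterion == c_ & cr$band == b]
  expect_equal(get("aapos2021", "ge4", "astigmatism_ge"), 1.75)
  expect_equal(get("aapos2021", "under4", "astigmatism_ge"), 3.00)
  expect_equal(get("aapos2021", "under4", "myopia_le"), -3.00)
  expect_equal(get("aapos2021", "ge4", "myopia_le"), -2.00)
  expect_equal(get("arnold_specific", "under4", "astigmatism_ge"), 3.75)
  expect_equal(get("arnold_medium", "ge4", "astigmatism_ge"), 2.50)
  expect_equal(get("arthur", "ge4", "hyperopia_ge"), 3.50)
  expect_equal(get("abcd", "ge4", "myopia_le"), -2.25)
  # single-row criteria repeat the same thresholds in both bands
  ms <- cr[cr$criterion == "matta_silbert", ]
  expect_equal(ms[ms$band == "under4", -3], ms[ms$band == "ge4", -3])
  expect_equal(ms$hyperopia_ge, c(1.25, 1.25))
  validate_criteria(cr)
})

test_that("criteria YAML round trips bit-exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria_yaml(builtin_criteria(), path)
  expect_identical(read_criteria_yaml(path), builtin_criteria())
})

test_that("classification applies age-banded thresholds to the worse eye", {
  # 2 D of cylinder at age 5: fails AAPOS (>=1.75) and Matta & Silbert
  # (>=1.00) but not Arnold Medium (>=2.50)
  child <- mini_child("a", age = 5, od = c(0, -2), os = c(0, 0))
  flags <- classify_cohort(validate_cohort(child))
  row <- function(cr) flags[flags$criterion == cr, ]
  expect_true(row("aapos2021")$astigmatism)
  expect_true(row("aapos2021")$referred)
  expect_false(row("arnold_medium")$referred)
  expect_true(row("matta_silbert")$astigmatism)
  # same child under 4: AAPOS astigmatism threshold is 3.00 there
  younger <- validate_cohort(dplyr::mutate(child, age_years = 3.5))
  expect_false(classify_cohort(younger)[
    classify_cohort(younger)$criterion == "aapos2021", ]$astigmatism)
})

test_that("device codes flag their category under every criterion", {
  child <- validate_cohort(mini_child("a", age = 3.5, od_status = "hyp"))
  flags <- classify_cohort(child)
  expect_true(all(flags$hyperopia))
  expect_true(all(flags$referred))
  expect_false(any(flags$astigmatism | flags$anisometropia | flags$unreadable))
  myo <- classify_cohort(validate_cohort(mini_child("b", od_status = "myo")))
  expect_true(all(myo$myopia))
  unread <- classify_cohort(validate_cohort(
    mini_child("c", od_status = "unreadable", os_status = "unreadable")))
  expect_true(all(unread$unreadable))
  expect_true(all(unread$referred))
  expect_false(any(unread$hyperopia))
})

test_that("plano children pass every criterion", {
  flags <- classify_cohort(validate_cohort(mini_child("a")))
  expect_false(any(flags$referred))
})

test_that("classification is invariant to cylinder transposition", {
  r <- random_refractions(60, seed = 3)
  minus <- normalize_to_minus_cylinder(r$sphere, r$cylinder, r$axis)
  make <- function(s, c_, a) {
    dplyr::bind_rows(lapply(seq_along(s), function(i) {
      row <- mini_child(sprintf("c%02d", i), age = 5,
                        od = c(s[i], c_[i]), os = c(0.25, 0))
      row$od_axis <- if (c_[i] != 0) a[i] else NA_real_
      row
    }))
  }
  f1 <- classify_cohort(validate_cohort(make(r$sphere, r$cylinder, r$axis)))
  f2 <- classify_cohort(validate_cohort(make(minus$sphere, minus$cylinder,
                                             minus$axis)))
  expect_equal(f1, f2)
})

test_that("stricter criteria flag subsets of looser criteria's children", {
  cohort <- generate_cohort(cohort_spec(n = c(public = 500, private = 500)),
                            seed = 42)
  flags <- classify_cohort(cohort)
  cr <- builtin_criteria()
  col_of <- c(hyperopia = "hyperopia_ge", myopia = "myopia_le",
              astigmatism = "astigmatism_ge", anisometropia = "anisometropia_ge")
  crits <- unique(cr$criterion)
  for (cat in names(col_of)) {
    for (a in crits) for (b in crits) {
      if (a == b) next
      ta <- cr[cr$criterion == a, ][[col_of[[cat]]]]
      tb <- cr[cr$criterion == b, ][[col_of[[cat]]]]
      stricter <- if (cat == "myopia") all(ta <= tb) else all(ta >= tb)
      if (!stricter) next
      set_a <- flags$child_id[flags$criterion == a & flags[[cat]]]
      set_b <- flags$child_id[flags$criterion == b & flags[[cat]]]
      expect_true(all(set_a %in% set_b),
                  label = sprintf("%s: %s subset of %s", cat, a, b))
    }
  }
})

test_that("dropping the unreadable child decrements only the referral count", {
  cohort <- validate_cohort(dplyr::bind_rows(
    mini_child("a", od = c(0, -2.5)),
    mini_child("b", od_status = "unreadable", os_status = "unreadable"),
    mini_child("c")
  ))
  with_u <- tabulate_rates(classify_cohort(cohort))
  without <- tabulate_rates(classify_cohort(cohort[cohort$child_id != "b", ]))
  for (cat in c("hyperopia", "myopia", "astigmatism", "anisometropia")) {
    expect_equal(with_u$count[with_u$category == cat],
                 without$count[without$category == cat])
  }
  expect_equal(with_u$count[with_u$category == "referred"] - 1,
               without$count[without$category == "referred"])
})

test_that("rate tabulation rounds half-up at the requested precision", {
  expect_equal(percent_round(69, 308, 0), 22)
  expect_equal(percent_round(93, 308, 1), 30.2)
  expect_equal(percent_round(0, 308, 1), 0)
  flags <- classify_cohort(fixture()$cohort)
  rates <- tabulate_rates(flags, decimals = 1)
  expect_equal(rates$percent,
               percent_round(rates$count, rates$n, 1))
})
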