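test_that("threshold chains sort thresholds with monotone criteria sets", {
  cr <- builtin_criteria()
  hyp <- threshold_chain(cr, "hyperopia", "ge4")
  expect_equal(hyp$lower, c(1.25, 2.50, 3.00, 3.50, 4.00))
  expect_equal(hyp$criteria[[1]], "matta_silbert")
  expect_setequal(hyp$criteria[[4]],
                  c("matta_silbert", "abcd", "arnold_medium",
                    "arnold_specific", "arthur"))
  expect_setequal(hyp$criteria[[5]], unique(cr$criterion))
  # activity is monotone along the chain
  for (i in 2:nrow(hyp)) {
    expect_true(all(hyp$criteria[[i - 1]] %in% hyp$criteria[[i]]))
  }
  ast_u <- threshold_chain(cr, "astigmatism", "under4")
  expect_equal(ast_u$lower, c(1.00, 1.25, 2.25, 3.00, 3.50, 3.75))
  one <- threshold_chain(cr[cr$criterion == "arthur", ], "myopia", "ge4")
  expect_equal(nrow(one), 1)
  expect_equal(one$lower, 3.0)
})

test_that("category allocation reproduces counts by interval differences", {
  cr <- builtin_criteria()
  # hyperopia: numeric targets after removing the 7 HYP-coded children
  hyp <- solve_category_allocation(
    cr, "hyperopia",
    c(aapos2021 = 0, arthur = 3, arnold_medium = 4, arnold_specific = 3,
      matta_silbert = 31, abcd = 4))
  expect_equal(hyp$band, rep("any", 5))
  expect_equal(hyp$count, c(27L, 0L, 1L, 3L, 0L))
  ani <- solve_category_allocation(
    cr, "anisometropia",
    c(arthur = 17, abcd = 17, aapos2021 = 14, matta_silbert = 14,
      arnold_medium = 5, arnold_specific = 5))
  expect_equal(ani$count, c(3L, 9L, 5L))
  # cumulative sums reproduce each criterion's target exactly
  for (i in seq_len(nrow(ani))) {
    for (crit in ani$criteria[[i]]) {
      tot <- sum(ani$count[vapply(ani$criteria, function(s) crit %in% s,
                                  logical(1))])
      expect_equal(tot, c(arthur = 17, abcd = 17, aapos2021 = 14,
                          matta_silbert = 14, arnold_medium = 5,
                          arnold_specific = 5)[[crit]])
    }
  }
})

test_that("band-split allocation handles decoupled myopia orderings", {
  cr <- builtin_criteria()
  # Arthur is stricter than Arnold in the ge4 band but looser under 4;
  # Arthur 4 > Arnold 3 forces at least one under-4 placement
  myo <- solve_category_allocation(
    cr, "myopia",
    c(aapos2021 = 13, arthur = 4, arnold_medium = 3, arnold_specific = 3,
      matta_silbert = 25, abcd = 9))
  for (crit in unique(cr$criterion)) {
    tot <- sum(myo$count[vapply(myo$criteria, function(s) crit %in% s,
                                logical(1))])
    expect_equal(tot, c(aapos2021 = 13, arthur = 4, arnold_medium = 3,
                        arnold_specific = 3, matta_silbert = 25,
                        abcd = 9)[[crit]], label = crit)
  }
  expect_true(sum(myo$count[myo$band == "under4"]) >= 1)
})

test_that("infeasible targets raise a named infeasibility error", {
  cr <- builtin_criteria()
  # stricter criterion with a larger count on a shared band
  expect_error(solve_category_allocation(
    cr, "hyperopia",
    c(aapos2021 = 10, arthur = 3, arnold_medium = 4, arnold_specific = 3,
      matta_silbert = 2, abcd = 4)), "infeasible")
  # equal thresholds with unequal counts
  expect_error(solve_category_allocation(
    cr, "anisometropia",
    c(arthur = 17, abcd = 16, aapos2021 = 14, matta_silbert = 14,
      arnold_medium = 5, arnold_specific = 5)), "share threshold")
})

test_that("the overlap plan reaches the published union counts exactly", {
  plan <- plan_overlaps(builtin_criteria(), reconstruction_targets())
  expect_true(all(plan$union_residual == 0))
  # union residual accounting: baseline minus reductions equals target
  red <- rep(0, 6)
  names(red) <- names(plan$union_targets)
  for (i in seq_len(nrow(plan$moves))) {
    red <- red + plan$moves$count[i] * plan$moves$reduction[[i]][names(red)]
  }
  expect_equal(plan$baseline_union - red, plan$union_targets)
})

test_that("the reconstructed cohort reproduces every published margin", {
  res <- fixture()
  cohort <- res$cohort
  expect_equal(nrow(cohort), 308)
  expect_equal(sum(cohort$age_band == "under4"), 106)
  expect_equal(sum(cohort$age_band == "ge4"), 202)
  expect_equal(sum(cohort$school_type == "public"), 114)
  expect_equal(sum(cohort$school_type == "private"), 194)
  expect_equal(sum(cohort$wears_spectacles), 28)
  # 24 category-count equalities plus 6 union equalities
  expect_true(all(res$report$category_check$residual == 0))
  expect_true(all(res$report$union_check$residual == 0))
  # device codes as printed
  expect_equal(sum(cohort$od_status == "hyp" | cohort$os_status == "hyp"), 7)
  expect_equal(sum(cohort$od_status == "myo" | cohort$os_status == "myo"), 1)
  expect_equal(sum(cohort$od_status == "unreadable"), 2)
  # demographic margins
  expect_equal(sum(cohort$sex == "f" & cohort$school_type == "public"), 52)
  expect_equal(sum(cohort$grade == "nursery"), 46)
  expect_equal(sum(cohort$grade == "kg2"), 96)
})

test_that("reconstruction is deterministic down to the CSV bytes", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(reconstruct_cohort()$cohort, p1)
  write_cohort(reconstruct_cohort()$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_gt(length(readLines(p1)), 300)
})

test_that("perturbing a region count shifts exactly its criteria's totals", {
  cr <- builtin_criteria()
  targets <- c(arthur = 17, abcd = 17, aapos2021 = 14, matta_silbert = 14,
               arnold_medium = 5, arnold_specific = 5)
  base <- solve_category_allocation(cr, "anisometropia", targets)
  # add one child beyond every criterion's threshold: all totals rise by 1
  bumped <- targets + ifelse(names(targets) %in% base$criteria[[nrow(base)]], 1, 0)
  new <- solve_category_allocation(cr, "anisometropia", bumped)
  expect_equal(new$count - base$count, c(rep(0L, nrow(base) - 1), 1L))
})
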