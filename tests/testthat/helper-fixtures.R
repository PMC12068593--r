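# Reconstruction is deterministic; build it once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function() {
  if (is.null(.fixture_cache$res)) {
    .fixture_cache$res <- reconstruct_cohort()
  }
  .fixture_cache$res
}

# A tiny hand-built cohort: one child per construction.
mini_child <- function(id, age = 5, od = c(0, 0), os = c(0, 0),
                       od_status = "numeric", os_status = "numeric",
                       school = "public", spectacles = FALSE) {
  tibble::tibble(
    child_id = id, age_years = age, school_type = school, grade = "kg2",
    sex = "f", wears_spectacles = spectacles,
    od_status = od_status,
    od_sphere = if (od_status == "numeric") od[1] else NA_real_,
    od_cylinder = if (od_status == "numeric") od[2] else NA_real_,
    od_axis = if (od_status == "numeric" && od[2] != 0) 90 else NA_real_,
    os_status = os_status,
    os_sphere = if (os_status == "numeric") os[1] else NA_real_,
    os_cylinder = if (os_status == "numeric") os[2] else NA_real_,
    os_axis = if (os_status == "numeric" && os[2] != 0) 90 else NA_real_
  )
}

# Random valid numeric refractions for property tests.
random_refractions <- function(n, seed) {
  set.seed(seed)
  # bounded so that both cylinder conventions stay inside the device
  # range (transposing adds a positive cylinder to the sphere)
  tibble::tibble(
    sphere = round(stats::runif(n, -4, 2) * 4) / 4,
    cylinder = round(stats::runif(n, -3, 3) * 4) / 4,
    axis = sample(1:180, n, replace = TRUE)
  )
}
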