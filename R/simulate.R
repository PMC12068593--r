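#' Specification of a stochastic screening cohort
#'
#' Parameters of the generative model used for property testing and
#' power exploration: a two-stratum (public/private school) cohort in
#' which each child's pair of spherical equivalents is drawn from a
#' bivariate normal with interocular correlation `rho`, cylinders are
#' drawn per eye from a lognormal magnitude model with a given
#' prevalence, and device status codes (HYP/MYO/unreadable) replace the
#' reading with stratified Bernoulli probability.
#'
#' Default spherical-equivalent moments are 0.82 +- 1.00 D (public) and
#' 0.45 +- 0.67 D (private); `se_mean`/`se_sd` are calibrated at the
#' child level (the mean of the two eyes), so the per-eye marginal SD is
#' inflated by 1/sqrt((1+rho)/2). The astigmatism magnitude model is
#' lognormal with median 0.75 D and log-SD 0.45, whose >= 1.75 D tail
#' averages about 2.1 D. The under-4 fractions and code and spectacle
#' rates default to the packaged reconstruction margins.
#'
#' @param n named vector: children per school stratum.
#' @param frac_under4 named vector: fraction of each stratum younger
#'   than 4 years.
#' @param se_mean,se_sd named vectors: per-stratum child-level SE
#'   moments in diopters.
#' @param rho interocular SE correlation in `[0, 1]`.
#' @param cyl_prevalence probability an eye has a nonzero cylinder.
#' @param cyl_meanlog,cyl_sdlog lognormal parameters of |cylinder|.
#' @param code_rates named vector: per-child probabilities of the `hyp`,
#'   `myo` and `unreadable` device codes (both eyes coded).
#' @param spectacle_rate named vector per stratum.
#' @param device_range,max_cylinder device limits; numeric draws are
#'   clipped to them.
#' @return A list of class `arf_cohort_spec`.
#' @export
cohort_spec <- function(n = c(public = 114, private = 194),
                        frac_under4 = c(public = 13 / 114, private = 93 / 194),
                        se_mean = c(public = 0.82, private = 0.45),
                        se_sd = c(public = 1.00, private = 0.67),
                        rho = 0.9,
                        cyl_prevalence = 0.30,
                        cyl_meanlog = log(0.75),
                        cyl_sdlog = 0.45,
                        code_rates = c(hyp = 7 / 308, myo = 1 / 308,
                                       unreadable = 2 / 308),
                        spectacle_rate = c(public = 2 / 114,
                                           private = 26 / 194),
                        device_range = c(-7, 5),
                        max_cylinder = 7) {
  stopifnot(all(n >= 0), all(se_sd > 0), rho >= 0, rho <= 1,
            cyl_prevalence >= 0, cyl_prevalence <= 1,
            all(code_rates >= 0), sum(code_rates) <= 1,
            all(frac_under4 >= 0), all(frac_under4 <= 1),
            all(spectacle_rate >= 0), all(spectacle_rate <= 1))
  structure(list(
    n = n, frac_under4 = frac_under4, se_mean = se_mean, se_sd = se_sd,
    rho = rho, cyl_prevalence = cyl_prevalence, cyl_meanlog = cyl_meanlog,
    cyl_sdlog = cyl_sdlog, code_rates = code_rates,
    spectacle_rate = spectacle_rate, device_range = device_range,
    max_cylinder = max_cylinder
  ), class = "arf_cohort_spec")
}

#' Generate a stochastic screening cohort
#'
#' Draws a cohort under a [cohort_spec()]: child-level SE means come
#' from a normal with the stratum moments and are split into two
#' correlated per-eye SEs; each eye's cylinder magnitude is drawn from
#' the lognormal model (minus-cylinder convention, uniform axis) and the
#' sphere is back-computed so the eye's spherical equivalent equals the
#' drawn value; device codes overwrite both eyes with the stratified
#' rates. Fully reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A validated cohort tibble.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "arf_cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  strata <- names(spec$n)
  rows <- lapply(strata, function(sch) {
    n <- spec$n[[sch]]
    if (n == 0) return(NULL)
    # per-eye marginal sd such that the two-eye mean has the target sd
    sd_eye <- spec$se_sd[[sch]] / sqrt((1 + spec$rho) / 2)
    z1 <- stats::rnorm(n)
    z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * stats::rnorm(n)
    se_od <- spec$se_mean[[sch]] + sd_eye * z1
    se_os <- spec$se_mean[[sch]] + sd_eye * z2
    cyl <- function() {
      has <- stats::runif(n) < spec$cyl_prevalence
      mag <- stats::rlnorm(n, spec$cyl_meanlog, spec$cyl_sdlog)
      ifelse(has, -pmin(mag, spec$max_cylinder), 0)
    }
    cyl_od <- cyl(); cyl_os <- cyl()
    clamp <- function(x) pmin(pmax(x, spec$device_range[1]), spec$device_range[2])
    sph_od <- clamp(se_od - cyl_od / 2)
    sph_os <- clamp(se_os - cyl_os / 2)
    u <- stats::runif(n)
    cr <- spec$code_rates
    status <- ifelse(u < cr[["hyp"]], "hyp",
              ifelse(u < cr[["hyp"]] + cr[["myo"]], "myo",
              ifelse(u < sum(cr), "unreadable", "numeric")))
    num <- status == "numeric"
    under4 <- stats::runif(n) < spec$frac_under4[[sch]]
    axis_draw <- function(cylv) ifelse(cylv != 0, ceiling(stats::runif(n) * 180), NA_real_)
    tibble::tibble(
      child_id = NA_character_,
      age_years = ifelse(under4, 3.5, 5),
      school_type = sch,
      grade = "kg2",
      sex = rep(c("f", "m"), length.out = n),
      wears_spectacles = stats::runif(n) < spec$spectacle_rate[[sch]],
      od_status = status,
      od_sphere = ifelse(num, sph_od, NA_real_),
      od_cylinder = ifelse(num, cyl_od, NA_real_),
      od_axis = ifelse(num, axis_draw(cyl_od), NA_real_),
      os_status = status,
      os_sphere = ifelse(num, sph_os, NA_real_),
      os_cylinder = ifelse(num, cyl_os, NA_real_),
      os_axis = ifelse(num, axis_draw(cyl_os), NA_real_)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$child_id <- sprintf("s%05d", seq_len(nrow(out)))
  validate_cohort(out, device_range = spec$device_range,
                  max_cylinder = spec$max_cylinder)
}

#' Estimate generative parameters from a cohort
#'
#' Recovers per-stratum child-level spherical-equivalent moments (over
#' children with two numeric readings, child SE = mean of the two eyes)
#' and, optionally, the category prevalences under one named criterion.
#'
#' @param cohort a cohort tibble.
#' @param criteria a criteria tibble used for the prevalence block.
#' @param criterion name of the criterion to tabulate under; `NULL`
#'   skips the prevalence block.
#' @param convention a [metric_convention()].
#' @return A list with `moments` (tibble: stratum, n_usable, se_mean,
#'   se_sd) and `prevalence` (a [tabulate_rates()] tibble or `NULL`).
#' @export
estimate_parameters <- function(cohort, criteria = builtin_criteria(),
                                criterion = "aapos2021",
                                convention = metric_convention()) {
  m <- add_refraction_metrics(cohort, convention)
  usable <- dplyr::filter(m, .data$od_status == "numeric",
                          .data$os_status == "numeric") |>
    dplyr::mutate(child_se = (.data$od_se + .data$os_se) / 2)
  moments <- usable |>
    dplyr::group_by(stratum = .data$school_type) |>
    dplyr::summarise(n_usable = dplyr::n(),
                     se_mean = mean(.data$child_se),
                     se_sd = stats::sd(.data$child_se), .groups = "drop")
  if (any(moments$n_usable < 2) || nrow(moments) == 0) {
    stop("need at least 2 children with two numeric readings per stratum")
  }
  prevalence <- NULL
  if (!is.null(criterion)) {
    crit <- criteria[criteria$criterion == criterion, ]
    if (nrow(crit) == 0) stop("unknown criterion: ", criterion)
    prevalence <- tabulate_rates(classify_cohort(cohort, crit, convention))
  }
  list(moments = moments, prevalence = prevalence)
}
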