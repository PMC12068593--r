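categories4 <- c("hyperopia", "myopia", "astigmatism", "anisometropia")

threshold_column <- c(hyperopia = "hyperopia_ge", myopia = "myopia_le",
                      astigmatism = "astigmatism_ge",
                      anisometropia = "anisometropia_ge")

quarter_ceil <- function(x) ceiling(x / 0.25 - 1e-9) * 0.25

# Deterministic representative diopter value for a half-open magnitude
# region [lower, upper): the 0.25-grid point nearest the midpoint (ties
# to the lower value); unbounded top regions use lower + 0.50.
region_value <- function(lower, upper) {
  if (!is.finite(upper)) return(lower + 0.5)
  cand <- seq(quarter_ceil(lower), upper - 1e-9, by = 0.25)
  if (length(cand) == 0) return((lower + upper) / 2)
  mid <- (lower + upper) / 2
  cand[order(abs(cand - mid), cand)][1]
}

#' Threshold chain of a category across criteria
#'
#' Sorts the distinct thresholds that the criteria apply to one
#' refractive-error category in one age band (by magnitude for myopia)
#' and labels each half-open region between adjacent thresholds with the
#' exact set of criteria that flag a value falling in it. Criterion
#' activity is monotone along the chain: once active at a threshold, a
#' criterion stays active in every stricter region.
#'
#' @param criteria a criteria tibble (see [builtin_criteria()]).
#' @param category one of `"hyperopia"`, `"myopia"`, `"astigmatism"`,
#'   `"anisometropia"`.
#' @param band `"under4"` or `"ge4"`.
#' @return A tibble with columns `region`, `lower`, `upper` (magnitude
#'   diopters, `Inf` for the top region), `criteria` (list column of
#'   criterion names active in the region) and `value` (the
#'   representative diopter magnitude used when materializing a reading
#'   in the region).
#' @export
threshold_chain <- function(criteria, category, band) {
  category <- match.arg(category, categories4)
  rows <- criteria[criteria$band == band, ]
  if (nrow(rows) == 0) stop("no criteria for band ", band)
  thr <- abs(rows[[threshold_column[[category]]]])
  names(thr) <- rows$criterion
  levels_ <- sort(unique(thr))
  n <- length(levels_)
  upper <- c(levels_[-1], Inf)
  tibble::tibble(
    region = seq_len(n),
    lower = levels_,
    upper = upper,
    criteria = lapply(seq_len(n), function(i) names(thr)[thr <= levels_[i]]),
    value = vapply(seq_len(n), function(i) region_value(levels_[i], upper[i]),
                   numeric(1))
  )
}

band_free_category <- function(criteria, category) {
  col <- threshold_column[[category]]
  u <- criteria[criteria$band == "under4", c("criterion", col)]
  g <- criteria[criteria$band == "ge4", c("criterion", col)]
  m <- merge(u, g, by = "criterion")
  all(m[[2]] == m[[3]])
}

# --- integer allocation of category counts onto threshold-chain regions ---

# Search for per-criterion under4 cumulative counts consistent with the
# numeric category targets, the nested-chain monotonicity of both bands'
# cumulative counts, and any minimum region occupancies requested by the
# overlap planner. Values are explored in ascending order so the first
# solution places as few children as possible in the under4 band
# ("prefer ge4, then smallest magnitudes" tie-break). Returns NULL when
# infeasible.
allocate_split <- function(targets, thr_u, thr_g, chain_u, chain_g,
                           min_regions = list()) {
  crits <- names(targets)
  lev_u <- sort(unique(thr_u))
  groups <- lapply(lev_u, function(l) crits[thr_u == l])
  k <- length(groups)
  region_counts <- function(chain, cums) {
    # cums: cumulative count at each chain level, in chain order
    c(cums[-length(cums)] - cums[-1], cums[length(cums)])
  }
  min_for <- function(band, idx) {
    key <- paste0(band, ":", idx)
    if (!is.null(min_regions[[key]])) min_regions[[key]] else 0L
  }
  best <- NULL
  u_val <- numeric(k)
  check_leaf <- function() {
    u_c <- stats::setNames(numeric(length(crits)), crits)
    for (i in seq_len(k)) u_c[groups[[i]]] <- u_val[i]
    g_c <- targets - u_c
    if (any(g_c < 0)) return(NULL)
    # cumulative count at each chain level = subtotal of any criterion
    # whose threshold sits exactly at that level (they must all agree)
    cum_at <- function(chain, thr, vals) {
      out <- numeric(nrow(chain))
      for (i in seq_len(nrow(chain))) {
        at_level <- crits[thr == chain$lower[i]]
        if (length(unique(vals[at_level])) > 1) return(NULL)
        out[i] <- vals[at_level][1]
      }
      out
    }
    cum_u <- cum_at(chain_u, thr_u, u_c)
    cum_g <- cum_at(chain_g, thr_g, g_c)
    if (is.null(cum_u) || is.null(cum_g)) return(NULL)
    if (is.unsorted(rev(cum_u)) || is.unsorted(rev(cum_g))) return(NULL)
    rc_u <- region_counts(chain_u, cum_u)
    rc_g <- region_counts(chain_g, cum_g)
    if (any(rc_u < 0) || any(rc_g < 0)) return(NULL)
    for (i in seq_along(rc_u)) if (rc_u[i] < min_for("under4", i)) return(NULL)
    for (i in seq_along(rc_g)) if (rc_g[i] < min_for("ge4", i)) return(NULL)
    list(under4 = rc_u, ge4 = rc_g)
  }
  dfs <- function(i) {
    if (!is.null(best)) return()
    if (i > k) {
      res <- check_leaf()
      if (!is.null(res)) best <<- res
      return()
    }
    mem <- groups[[i]]
    ub <- min(targets[mem])
    if (i > 1) ub <- min(ub, u_val[i - 1])
    lb <- 0
    # ge4-chain monotonicity against already-assigned groups
    for (j in seq_len(i - 1)) {
      for (c_new in mem) {
        for (c_old in groups[[j]]) {
          tg_new <- thr_g[c_new]; tg_old <- thr_g[c_old]
          rhs <- targets[c_new] - targets[c_old] + u_val[j]
          if (tg_old < tg_new) lb <- max(lb, rhs)
          if (tg_old > tg_new) ub <- min(ub, rhs)
          if (tg_old == tg_new) { lb <- max(lb, rhs); ub <- min(ub, rhs) }
        }
      }
    }
    if (lb > ub) return()
    for (v in lb:ub) {
      u_val[i] <<- v
      dfs(i + 1)
      if (!is.null(best)) return()
    }
  }
  dfs(1)
  best
}

#' Allocate per-criterion category counts onto chain regions
#'
#' Distributes a category's per-criterion numeric target counts over the
#' threshold-chain regions of both age bands so that every criterion's
#' cumulative count over the regions at or beyond its threshold
#' reproduces its target exactly. For categories whose thresholds agree
#' across bands the allocation is forced by difference-taking along the
#' single nested chain; where the bands decouple the criteria orderings
#' (e.g. myopia) a small integer feasibility search over per-band
#' subtotals is run, preferring the ge4 band, then smaller magnitudes.
#'
#' @param criteria a criteria tibble.
#' @param category the refractive-error category.
#' @param targets named integer vector of numeric-reading target counts
#'   per criterion (device-code children excluded).
#' @param min_regions optional named list (`"band:region"` -> count) of
#'   minimum occupancies, used by the overlap planner.
#' @return A tibble with columns `category`, `band` (`"any"` when the
#'   thresholds agree across bands), `region`, `lower`, `upper`,
#'   `criteria`, `value`, `count`; or an error naming the violated
#'   cumulative constraint when the targets are infeasible.
#' @export
solve_category_allocation <- function(criteria, category, targets,
                                      min_regions = list()) {
  category <- match.arg(category, categories4)
  crits <- unique(criteria$criterion)
  if (!setequal(names(targets), crits)) {
    stop("targets must name every criterion exactly once")
  }
  targets <- targets[crits]
  if (any(targets < 0)) stop("negative numeric target for category ", category)
  col <- threshold_column[[category]]
  thr_band <- function(b) {
    r <- criteria[criteria$band == b, ]
    stats::setNames(abs(r[[col]]), r$criterion)[crits]
  }
  thr_u <- thr_band("under4"); thr_g <- thr_band("ge4")
  chain_u <- threshold_chain(criteria, category, "under4")
  chain_g <- threshold_chain(criteria, category, "ge4")
  if (band_free_category(criteria, category)) {
    # single chain; cumulative counts forced by the targets
    cums <- vapply(seq_len(nrow(chain_g)), function(i) {
      mem <- chain_g$criteria[[i]]
      at_level <- mem[thr_g[mem] == chain_g$lower[i]]
      vals <- unique(targets[at_level])
      if (length(vals) > 1) {
        stop(sprintf(
          "infeasible %s targets: criteria %s share threshold %.2f but have counts %s",
          category, paste(at_level, collapse = ", "), chain_g$lower[i],
          paste(targets[at_level], collapse = ", ")))
      }
      vals
    }, numeric(1))
    counts <- c(cums[-length(cums)] - cums[-1], cums[length(cums)])
    if (any(counts < 0)) {
      i <- which(counts < 0)[1]
      stop(sprintf(
        "infeasible %s targets: cumulative count must be non-increasing with strictness, violated between thresholds %.2f and %.2f",
        category, chain_g$lower[i], chain_g$lower[min(i + 1, nrow(chain_g))]))
    }
    for (i in seq_along(counts)) {
      key <- paste0("any:", i)
      if (!is.null(min_regions[[key]]) && counts[i] < min_regions[[key]]) {
        stop(sprintf("infeasible %s region minimum at region %d", category, i))
      }
    }
    return(dplyr::mutate(chain_g, category = category, band = "any",
                         count = as.integer(counts), .before = 1))
  }
  res <- allocate_split(targets, thr_u, thr_g, chain_u, chain_g, min_regions)
  if (is.null(res)) {
    stop(sprintf(
      "infeasible %s targets: no band split satisfies both bands' cumulative chain constraints (and requested region minimums)",
      category))
  }
  dplyr::bind_rows(
    dplyr::mutate(chain_u, category = category, band = "under4",
                  count = as.integer(res$under4), .before = 1),
    dplyr::mutate(chain_g, category = category, band = "ge4",
                  count = as.integer(res$ge4), .before = 1)
  )
}

#' Published count targets for cohort reconstruction
#'
#' Loads the packaged YAML of marginal counts that the deterministic
#' reconstruction reproduces: cohort size and age-band/school margins,
#' per-criterion category and referral (union) counts, device-code
#' counts, the school-stratified referral and spectacle counts, and the
#' demographic margins.
#'
#' @param path optional path to a targets YAML; defaults to the packaged
#'   file.
#' @return A nested list of targets.
#' @export
reconstruction_targets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reconstruction_targets.yaml",
                        package = "amblyref")
  }
  yaml::read_yaml(path)
}

# --- overlap planning ------------------------------------------------------

# A move template places one child carrying findings in 2-3 categories,
# chosen so the child is double-counted (and therefore merged) exactly
# for the criteria shared between its findings' regions. `slots` name a
# (category, criteria-set) region; `build` returns the concrete eye
# readings. Sets reference the built-in criterion names; templates whose
# regions do not exist under the supplied criteria are skipped.
overlap_move_templates <- function() {
  ms <- "matta_silbert"; ar <- "arthur"; aa <- "aapos2021"
  am <- "arnold_medium"; as_ <- "arnold_specific"; ab <- "abcd"
  all6 <- c(ms, ar, aa, am, as_, ab)
  list(
    list(name = "hyp_high + astig_top + aniso_top", band = "ge4",
         slots = list(c_slot("hyperopia", setdiff(all6, aa)),
                      c_slot("astigmatism", all6),
                      c_slot("anisometropia", all6)),
         build = function() child_eyes(od = c(3.75, -3.25), os = c(0.25, 0))),
    list(name = "astig_top + aniso_top", band = "ge4",
         slots = list(c_slot("astigmatism", all6),
                      c_slot("anisometropia", all6)),
         build = function() child_eyes(od = c(0.875, -3.25), os = c(1, 0))),
    list(name = "astig_tra + aniso_mid", band = "ge4",
         slots = list(c_slot("astigmatism", c(ms, ar, aa)),
                      c_slot("anisometropia", c(ms, ar, aa, ab))),
         build = function() child_eyes(od = c(0.5, -2), os = c(1, 0))),
    list(name = "astig_trb_u + myo_tb_u + aniso_low", band = "under4",
         slots = list(c_slot("astigmatism", c(ms, ar, ab)),
                      c_slot("myopia", c(ms, ab)),
                      c_slot("anisometropia", c(ar, ab))),
         build = function() child_eyes(od = c(-1.25, -2.5), os = c(-1.5, 0))),
    list(name = "astig_trb_u + myo_tb_u", band = "under4",
         slots = list(c_slot("astigmatism", c(ms, ar, ab)),
                      c_slot("myopia", c(ms, ab))),
         build = function() child_eyes(od = c(-1.25, -2.5), os = c(-2.5, 0))),
    list(name = "astig_tr + aniso_mid", band = "ge4",
         slots = list(c_slot("astigmatism", c(ms, ar)),
                      c_slot("anisometropia", c(ms, ar, aa, ab))),
         build = function() child_eyes(od = c(1.125, -1.5), os = c(-0.875, 0))),
    list(name = "hyp_low + aniso_mid", band = "ge4",
         slots = list(c_slot("hyperopia", ms),
                      c_slot("anisometropia", c(ms, ar, aa, ab))),
         build = function() child_eyes(od = c(1.75, 0), os = c(0.25, 0))),
    list(name = "hyp_low + astig_low", band = "ge4",
         slots = list(c_slot("hyperopia", ms), c_slot("astigmatism", ms)),
         build = function() child_eyes(od = c(1.75, -1), os = c(1, 0))),
    list(name = "myo_low + astig_low", band = "ge4",
         slots = list(c_slot("myopia", ms), c_slot("astigmatism", ms)),
         build = function() child_eyes(od = c(-1, -1), os = c(-1.5, 0)))
  )
}

c_slot <- function(category, set) list(category = category, set = set)

child_eyes <- function(od, os) {
  list(od_sphere = od[1], od_cylinder = od[2],
       os_sphere = os[1], os_cylinder = os[2])
}

find_region <- function(alloc, band, set) {
  rows <- which((alloc$band == band | alloc$band == "any") &
                  vapply(alloc$criteria, setequal, logical(1), y = set))
  if (length(rows) == 0) NULL else rows[1]
}

#' Plan multi-category children to meet union (referral) targets
#'
#' Category counts fix how many children carry each finding, but the
#' printed referral counts (the union over categories) are smaller than
#' the category sums whenever children carry several findings at once.
#' Starting from the category allocation, this planner assigns
#' co-occurring findings to single children, drawing from an ordered
#' catalogue of feasible combinations (strictest criteria first). Each
#' move is taken as often as the remaining union deficits allow without
#' overshooting any criterion and as often as region capacities permit
#' -- for band-split categories capacity is established by re-running
#' the allocator with the required region minimum. Residual union
#' deficits are reported, never silently dropped; for the packaged
#' targets the plan is exact.
#'
#' @param criteria a criteria tibble (the built-in six; templates that
#'   reference absent regions are skipped).
#' @param targets a targets list from [reconstruction_targets()].
#' @return A list with the final `allocations` (per category), the
#'   `moves` tibble (template, count), consumed region occupancies,
#'   per-criterion `union_residual`, and the numeric category targets.
#' @export
plan_overlaps <- function(criteria, targets) {
  crits <- unique(criteria$criterion)
  cc <- dplyr::bind_rows(lapply(targets$criteria_counts, tibble::as_tibble))
  if (!setequal(cc$criterion, crits)) {
    stop("criteria_counts must cover exactly the supplied criteria")
  }
  codes <- targets$codes
  numeric_targets <- function(category) {
    v <- stats::setNames(cc[[category]], cc$criterion)[crits]
    if (category == "hyperopia") v <- v - codes$hyp
    if (category == "myopia") v <- v - codes$myo
    if (any(v < 0)) {
      stop("device-code count exceeds the ", category, " target")
    }
    v
  }
  num_targets <- lapply(stats::setNames(categories4, categories4),
                        numeric_targets)
  union_targets <- stats::setNames(cc$union, cc$criterion)[crits]
  baseline <- stats::setNames(
    rowSums(sapply(categories4, function(cat) cc[[cat]])) +
      codes$unreadable, cc$criterion)[crits]
  need <- pmax(baseline - union_targets, 0)
  unreachable <- pmin(baseline - union_targets, 0)

  min_regions <- lapply(stats::setNames(categories4, categories4),
                        function(x) list())
  alloc_for <- function(category) {
    solve_category_allocation(criteria, category, num_targets[[category]],
                              min_regions[[category]])
  }
  allocations <- lapply(stats::setNames(categories4, categories4), alloc_for)

  moves <- list()
  for (tpl in overlap_move_templates()) {
    slot_rows <- lapply(tpl$slots, function(s) {
      idx <- find_region(allocations[[s$category]], tpl$band, s$set)
      if (is.null(idx)) return(NULL)
      list(category = s$category, idx = idx,
           band = allocations[[s$category]]$band[idx],
           region = allocations[[s$category]]$region[idx], set = s$set)
    })
    if (any(vapply(slot_rows, is.null, logical(1)))) next
    # union reduction per criterion: one less child for every extra slot
    # it flags on the merged child
    slot_sets <- lapply(slot_rows, `[[`, "set")
    r <- vapply(crits, function(cr) {
      max(0L, sum(vapply(slot_sets, function(s) cr %in% s, logical(1))) - 1L)
    }, integer(1))
    if (all(r == 0)) next
    k <- min(floor(need[r > 0] / r[r > 0]))
    if (k <= 0) next
    # capacity: every slot's region must be able to hold k more children
    k_cap <- function(k_try) {
      for (s in slot_rows) {
        cat <- s$category
        key <- paste0(s$band, ":", s$region)
        cur <- min_regions[[cat]][[key]] %||% 0L
        trial <- min_regions[[cat]]
        trial[[key]] <- cur + k_try
        ok <- tryCatch({
          solve_category_allocation(criteria, cat, num_targets[[cat]], trial)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) return(FALSE)
      }
      TRUE
    }
    while (k > 0 && !k_cap(k)) k <- k - 1
    if (k == 0) next
    for (s in slot_rows) {
      key <- paste0(s$band, ":", s$region)
      cur <- min_regions[[s$category]][[key]] %||% 0L
      min_regions[[s$category]][[key]] <- cur + k
    }
    need <- need - k * r
    moves[[length(moves) + 1]] <- tibble::tibble(
      template = tpl$name, band = tpl$band, count = k,
      slots = list(slot_rows), reduction = list(r), build = list(tpl$build)
    )
  }
  allocations <- lapply(stats::setNames(categories4, categories4), alloc_for)
  list(
    allocations = allocations,
    moves = dplyr::bind_rows(moves),
    consumed = min_regions,
    union_targets = union_targets,
    union_residual = need + unreachable,
    numeric_targets = num_targets,
    baseline_union = baseline
  )
}
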