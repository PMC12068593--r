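---
title: "Referral criteria for pediatric photorefraction screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Referral criteria for pediatric photorefraction screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amblyref)
library(dplyr)
```

## The problem

Automated photoscreeners such as the Plusoptix A12 estimate each eye's
refraction (sphere, cylinder, axis) non-invasively in a few seconds, which
makes them attractive for school-based amblyopia screening in children aged
roughly 3–6 years. A screening program must then decide which readings
trigger referral for a full ophthalmic examination. Several threshold sets
are in use — examination-failure criteria such as the AAPOS 2021 age-based
levels and Arthur's criteria, and device-specific instrument referral
criteria (Arnold medium and specific, Matta & Silbert, Alaska Blind Child
Discovery) — and the choice changes the referral rate substantially, because
the thresholds for hyperopia, myopia, astigmatism and anisometropia differ
by up to a factor of three between sets.

`amblyref` implements the full comparison pipeline: refractive algebra and
cohort I/O, declarative criteria, per-child classification, paired-proportion
statistics (Cochran's Q omnibus plus McNemar post-hoc tests, since the same
children are classified under every criterion), school-type stratification,
a deterministic cohort reconstruction from published marginal count tables,
and a stochastic cohort simulator.

## Classification model

Each child contributes two eyes, each either a numeric reading or a device
status code (`hyp` for hyperopia beyond +5 D, `myo` for high myopia,
`unreadable`). All threshold logic runs on the minus-cylinder form, in which
the sphere is the most-plus meridional power. A criterion flags a child for:

* **hyperopia** when the worse eye's hyperopia metric is at or above the
  hyperopia threshold (default metric: most-plus meridian, i.e. the
  minus-cylinder sphere);
* **myopia** when the worse eye's myopia metric is at or below the myopia
  threshold (default: spherical equivalent, SE = sphere + cylinder/2);
* **astigmatism** when either eye's |cylinder| reaches the threshold;
* **anisometropia** when the interocular difference of the configured
  quantity (default: SE) reaches the threshold.

Published criteria rarely state which refraction component each threshold
applies to; `metric_convention()` therefore makes the choices explicit and
configurable. The defaults follow screening practice: hyperopia on the
most-plus meridian (consistent with describing a child with sphere just
above 4 D as hyperopic), myopia and anisometropia on spherical equivalents.
An eye showing `hyp` flags hyperopia and `myo` flags myopia under every
criterion — the codes mean the reading exceeded the device's measurable
range, which dominates every published threshold — but such eyes contribute
no cylinder or anisometropia information. A child with an unreadable eye and
no flaggable numeric finding is marked unreadable and referred: a child the
device cannot measure cannot be cleared.

The age-band boundary is exactly 4.0 years (criteria published without age
bands repeat the same thresholds in both). A missing axis with a nonzero
cylinder is rejected rather than defaulted, since a silently invented axis
would corrupt the meridional metrics.

```{r classify-example}
cohort <- reconstruct_cohort()$cohort
cmp <- run_criteria_comparison(cohort)
cmp
```

## Statistics

The same children are classified under all six criteria, so marginal rates
are compared with tests for correlated proportions, implemented from first
principles (only distribution tail functions come from base R):

* `cochran_q()` — omnibus equality of k correlated proportions; the
  degenerate all-rows-constant case returns Q = 0, p = 1.
* `mcnemar_test()` — pairwise post-hoc tests on discordant pairs; exact
  binomial form below 25 discordant pairs, the continuity-corrected
  chi-square form above (the customary switch point). No multiplicity
  adjustment by default, matching how such post-hoc p-values are usually
  reported; a Bonferroni column is available.
* `chisq_2x2()` / `fisher_2x2()` — between-group comparisons, with
  `low_expected_rule()` selecting the exact test when more than 25% of
  expected cell counts fall below 5. The chi-square omits the Yates
  correction by default (the headline school-type comparison is significant
  under either choice); the correction is available via a flag.
* `welch_t_summary()` — two-group t test from summary moments, Welch form
  by default with the pooled form as an option.
* `min_sample_size()` — the single-proportion formula z²p(1−p)/e²,
  reporting the raw value together with floor and ceiling, so "at least n"
  phrasings can be checked without guessing the original rounding.
* `percent_round()` — half-up rounding in exact integer arithmetic, the
  convention used by the published tables this package reproduces.

## Deterministic cohort reconstruction

No per-child data are deposited for the cohort the package ships targets
for; only marginal tables are published (per-criterion category and referral
counts, age-band, school, grade, sex and spectacle margins, device-code
counts). The reconstruction solver builds a concrete 308-child cohort whose
classification reproduces those margins:

1. **Threshold chains** (`threshold_chain()`): for each category and age
   band, the distinct thresholds sorted by magnitude, each region labelled
   with the criteria active at or beyond it. Criterion activity is nested
   along a chain, so per-criterion cumulative counts translate into region
   counts by difference-taking.
2. **Category allocation** (`solve_category_allocation()`): category counts
   are hard constraints. Where thresholds agree across bands the allocation
   is forced; where the bands decouple the criteria orderings (myopia:
   Arthur is stricter than Arnold above 4 years but looser below) a small
   integer feasibility search over per-band subtotals runs, preferring the
   ≥4 band and smaller magnitudes — deterministic tie-breaks, so identical
   targets give byte-identical cohorts. Infeasible targets produce an error
   naming the violated cumulative constraint.
3. **Overlap planning** (`plan_overlaps()`): the printed referral counts
   are smaller than the category sums, so some children must carry several
   findings. The planner walks an ordered catalogue of feasible
   multi-finding child archetypes (e.g. a child with top-region astigmatism
   plus anisometropia, merged for every criterion; or an under-4 child
   whose moderate myopia and astigmatism merge only for the loosest
   criteria), taking each as often as the remaining union deficits allow
   without overshooting any criterion, with capacities validated through
   the allocator. Union residuals are always reported; for the packaged
   targets the plan is exact for all six criteria. The true joint structure
   is unidentifiable from marginals — the fixture reproduces the margins,
   not the (unknown) per-child joint distribution.
4. **Materialization** (`materialize_fixture()`): refraction values are
   placed at region representatives (0.25 D grid points nearest the region
   midpoint; unbounded regions at threshold + 0.50 D), fellow eyes are kept
   clear of every threshold, and each archetype is re-classified on the
   spot — any deviation from its intended flags is a hard error. The two
   children with no reading and no code are counted inside every
   criterion's referral total (they were all referred); the report also
   carries the union counts excluding them, since the published text does
   not pin that accounting down.
5. **Demographics**: school type is assigned to reproduce the stratified
   referral margins, spectacle wear to reproduce the spectacles-among-
   referred margins, grades and sex to match the published totals. The
   published per-category school breakdown is reported as achieved-versus-
   target, not forced: with referral margins fixed, those rows are not
   generally reachable simultaneously and the source tables do not
   constrain which children overlap.

```{r reconstruction-report}
reconstruct_cohort()$report
```

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, for property tests and power exploration. Per stratum,
child-level SE means are normal with the published school-type moments
(0.82 ± 1.00 D public, 0.45 ± 0.67 D private); the two eyes' SEs are
bivariate normal with correlation ρ = 0.9. The marginal per-eye SD is set
to sd/√((1+ρ)/2) so that the child-level (two-eye mean) SD matches the
target exactly — the published moments are child-level summaries, and this
calibration makes parameter recovery unbiased. The high default correlation
is also what keeps anisometropia prevalence at the published few-percent
level. Cylinder magnitudes are lognormal (median 0.75 D, log-SD 0.45, a
tail whose ≥1.75 D draws average ≈ 2.1 D, matching the published mean
astigmatism among flagged children) with 30% prevalence; spheres are
back-computed so each eye's SE equals its draw; device codes replace both
eyes at the published rates.

What the generator does *not* emulate: axis anatomy (axes are uniform),
age–refraction trends within a band, repeated captures per child, and any
dependence between astigmatism and SE. Tests that pass on generated cohorts
therefore validate the pipeline's logic and invariances, not the
epidemiology of any real population. Whether the published myopia and
astigmatism means are taken over flagged children only, and over worse eyes
or both, is not stated; the calibration above interprets them as
flagged-subgroup magnitudes.

```{r generator}
est <- estimate_parameters(generate_cohort(cohort_spec(), seed = 1))
est$moments
```

## Numerical choices

* Threshold comparisons are `>=`/`<=` on exact quarter-diopter values; no
  tolerance is needed because device output and thresholds share the
  0.25 D grid.
* `percent_round()` uses integer arithmetic, so x.5 boundaries at the last
  printed digit always round up, immune to binary floating point.
* Fisher's two-sided p sums hypergeometric probabilities ≤ the observed
  table's probability within a relative tolerance of 1e-7, the customary
  guard against ties lost to floating point.
* The allocator's search explores subtotals in ascending order, making the
  solver deterministic without an explicit objective function.
* Problem sizes in the test suite: exactness sweeps run over all McNemar
  tables with b + c ≤ 20 and all 2×2 Fisher tables with N ≤ 30; property
  tests use 1000 simulated children; parameter recovery uses 5000 children
  per stratum over ten seeds.

## Limitations

* Union-exact reconstruction is guaranteed only for the packaged targets;
  for other target sets the overlap planner is best-effort and reports
  residuals (its move catalogue is built around the six built-in criteria's
  chain structure).
* No gold-standard cycloplegic data exist for the reconstructed cohort, so
  sensitivity and specificity of the criteria cannot be computed — only
  referral and category rates.
* The printed percentages for anisometropia in the source tables are
  internally inconsistent with their counts at N = 308 (they correspond to
  the 298 children with readings); counts are treated as authoritative
  throughout.
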