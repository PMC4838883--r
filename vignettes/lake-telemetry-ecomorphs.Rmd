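---
title: "Methods: from acoustic fixes to ecomorph behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from acoustic fixes to ecomorph behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lakemorph` turns whole-lake acoustic-positioning data on polymorphic fish
into per-fish, per-month behavioural quantities: habitat selectivity,
kernel home ranges, movement rates, and a morphometric ecomorph
classification. This vignette is the package's own account of the models
it implements, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical decisions taken where
the underlying workflow leaves them open.

## The habitat model

The lake is a closed habitat: a bathymetry raster (metres of water,
positive down, `NA` = land) inside a simple boundary polygon, in a local
planar metre frame. No geographic CRS mathematics happens inside the
pipeline — at sub-kilometre lake scales the planar error is negligible,
and any projection belongs upstream. Grid indexing is half-open,
`[x0 + (j-1)s, x0 + js)`, with row 1 at the y-minimum, which makes edge
lookups unambiguous.

The **littoral zone** is lake area whose *total* depth is at or below the
littoral limit (default 8 m, boundary inclusive); everything else is
offshore. Availability `p` of each zone is its wet-cell area fraction.
Habitat use `r` of a fish in a month is simply the fraction of its
positions falling in the zone. Selectivity is Jacobs'
`D = (r - p) / (r + p - 2rp)`, which spans the full (-1, 1) range for any
availability when only two habitats are defined. Morph-level inference
uses the fish as the unit of replication: `D` is computed per fish-month,
and the morph-month mean carries a 95 % Student-t interval over fish
(`mean ± t(0.975, n-1) · SE`). A normal interval differs negligibly at
n ≥ 10 but is anti-conservative at the 3–5 fish months that occur in
practice, hence t. The verdict is `preferred` when the whole interval
lies above 0, `avoided` below 0, otherwise `neutral`; a single-fish
stratum reports `D` with the CI flagged unavailable rather than invented.

Two arithmetic conventions are worth stating because both appear in field
reports and they disagree:

* The QC report expresses exclusions **relative to the retained count**
  (`100 · excluded / valid`), not to the input count — that is the
  convention under which an exclusion count and its printed percentage
  are mutually consistent in the tracking literature this workflow
  follows.
* Morph-level means are **means of individual monthly means** (fish
  weighted equally within a month, months weighted equally within the
  year), never position-pooled means, so fish with denser fix records do
  not dominate.

## Position QC

Three filters run in a fixed order — positional-error metric
(`err ≤ err_max`), inside-the-boundary, tag-depth vs bathymetric-depth
concordance (`tag_depth ≤ bed + tol`) — and each fix is counted once at
its first failing filter, which keeps the accounting exactly
conservative. The error-metric threshold has no privileged default: it is
array-specific and must be chosen per study (`pipeline_config()` defaults
to 2.5, matching the synthetic observation model whose geometry factor
spans 1–2.5). The depth tolerance defaults to 1 m. Note one systematic
effect worth knowing: near steep shorelines, horizontal positioning error
moves near-bed fish onto shallower cells, so the depth-concordance filter
removes littoral fixes disproportionately and the estimated littoral use
of bottom-oriented fish is biased slightly low. The recovery tests
quantify this; it is a property of the filter, not a bug.

## Chronobiology

Sunrise and sunset come from the standard NOAA solar-position equations
with the conventional −0.833° horizon; dates where the sun never clears
(never drops below) the horizon are polar night (polar day). At 74.5° N
the computed winter interval is 8 Nov 2009 – 3 Feb 2010, an 88-day span
under endpoint-inclusive day counting — the only counting convention
consistent with that printed span. Civil dates use local time UTC+1
(Norwegian standard time, configurable); dawn and dusk are symmetric ±60
minute windows around sunrise/sunset (configurable) since no sharper
definition is standard, and the six diel categories partition every day
by construction.

## Home ranges

Per fish-month the workflow subsamples to 54 positions, stratified by
diel category × 3-hour block with **largest-remainder quotas**
proportional to each stratum's share of available fixes; ties in the
fractional remainders break by stratum order of first appearance
(deterministic), and a stratum short of its quota hands the shortfall
back for re-apportionment. The subsample size follows incremental-area
practice (the `incremental_area()` diagnostic reports the k at which the
K95 area stabilises to within 5 % over the next five increments).

The utilization distribution is a bivariate Gaussian product kernel with
a single bandwidth, `href = sigma_hat * n^(-1/6)`,
`sigma_hat = sqrt((var_x + var_y)/2)`, evaluated on a 5 m grid (matching
the 25 m² density-grid convention) over the point bounding box padded by
4h, and renormalised to unit mass on that grid. Isopleths are taken by
**cumulative-mass cell ranking** (sort cells by density, accumulate mass
to the probability, threshold cell included) rather than contouring:
grid-exact, deterministic, and trivially clippable. Clipping to the lake
boundary removes outside cells from the *area estimate* without
renormalising the distribution — it is the area that is clipped, not the
UD. K50 ⊆ K95 holds by construction. With degenerate point spreads the
bandwidth falls back to a 1 m floor with a warning rather than failing.

## Movement metrics

Displacement is horizontal (2-D) Euclidean distance between consecutive
fixes divided by elapsed time and fork length (BLs⁻¹); vertical movement
is reported separately as depth and distance-from-bed, so the two axes
are never conflated. Steps spanning more than 4 nominal transmission
intervals are skipped — straight-line speed over multi-hour gaps is
meaningless. Because fixes arrive roughly every 80 minutes, displacement
*underestimates* the true swim speed; the simulator's cruise/dwell
structure reproduces this and the test suite asserts the inequality.
Distances from the bed that come out slightly negative (within the depth
tolerance) clamp to zero. The morph test is a label permutation on
fish-level annual means with `p = (1 + #{perm ≥ obs}) / (1 + n_perm)` —
an exact-style substitute for a mixed-model morph effect, chosen because
it needs no distributional assumptions at these sample sizes; it does not
model the month × morph interaction.

## Morphometrics

Nine linear traits are size-corrected by ordinary least squares on fork
length; the discriminant analysis runs on the residuals. Stepwise forward
insertion picks, at each step, the trait minimising overall Wilks' Λ
(`det(W)/det(T)`), entering it only if the partial F-to-enter reaches
3.84 (the χ²₁ 5 % analogue; configurable). Canonical functions come from
the generalized eigenproblem of between- vs within-group scatter, scaled
to unit pooled within-group variance, at most `groups − 1` of them.
Classification uses equal priors — group sizes here are sampling
artefacts, not prevalences — and posterior ties (within 1e-9) break
deterministically toward the earlier group and are flagged. External
biological overrides (e.g. a gravid dwarf female classified with the
pelagic cluster) are applied only through an explicit override table and
flagged, never silently. A singular within-group scatter is
ridge-regularised with a warning.

## What the generators emulate — and what they do not

`make_lake()` builds a radial basin: a depth profile (`cone`:
`D(1-u)^m`; `bowl`: `D(1-u^k)`, `u` = relative radius) inside a shoreline
perturbed by low-amplitude seeded harmonics (≤ 5 % — enough to break the
circular symmetry that would otherwise hide kernel/clipping bugs). The
profile exponent is solved in closed form so the littoral fraction meets
its target (0.225 by default) — for the bowl,
`fraction = 1 - (1-z)^(2/k)` with `z = limit/max_depth`, which reduces to
`1 - (1 - z)` at exponent 2; a strict linear cone cannot reach 0.225 at
34 m depth, hence the apex-sharpness exponent. The perturbation is
tapered by `4u(1-u)` so the maximum depth and the shoreline stay exact.
The boundary polygon is traced as the exact outline of the wet-cell
union, so polygon area equals wet grid area identically and every wet
cell centre is strictly inside.

`simulate_track()` alternates **travel and dwell**: each relocation picks
a zone (littoral with probability `littoral_affinity` — a
destination-choice probability, *not* an area share), a
distance-discounted destination cell in it, swims there at cruise speed
(`cruise_factor ×` the net speed scale; the surplus is tortuosity), then
forages around the destination for an exponential dwell (mean 300 min,
OU jitter of 8 m). Same-zone legs travel along polar-interpolated paths
projected onto their zone, so a fish with affinity 1 is littoral at every
instant — exactly, not just on average. Depth mean-reverts to the
phenotype target and is capped 0.1 m above the bed. Long-run littoral
occupancy consequently tracks the affinity (0.5 → ≈ 0.45), not the 0.225
areal fraction. An ice interval removes cells shallower than the ice
thickness (default 1.1 m) from the destination pool, reproducing the
winter restriction of shallow habitat. `observe_track()` then emits
quasi-periodic transmissions (uniform jitter around 80 min), Bernoulli
detection, isotropic Gaussian position error scaled by a geometry factor
growing quadratically toward the shore, and tag depth quantised to the
0.22 m sensor resolution (50 m range); the `err` field records the
realised geometry factor. The hyperbolic positioning solver itself is
*not* simulated — error is injected directly, because the workflow treats
positioning as a black box and only filters its output. No acoustic
propagation, receiver clock drift, or multipath. Passing recovery tests
therefore show that the estimators invert *this* observation model; real
arrays have heavier-tailed, spatially structured error.

`simulate_morphometrics()` draws three groups with allometric traits,
trait-specific measurement noise (so the trait-on-length R² spans roughly
0.6–0.97, the band typical of such data), and group shape offsets.
Because size correction regresses over all groups pooled while group
membership correlates with fork length, part of the offsets is absorbed
into the fitted slope; the generator calibrates the offsets analytically
so the *residual-space* minimum pairwise centroid separation equals the
requested `separation_sd` (default 5 within-group s.d.).

## Study conditions used by the tests and the acceptance script

The recovery experiments run on a 0.71 km², 34 m, 22.5 %-littoral basin
at 10 m cells, truth tracks at 60 s resolution:

* selectivity — 10 fish per morph, affinities 0.7 vs 0.3, six 30-day
  months (12 morph-month strata). A verdict counts as matching the truth
  when it is `preferred`/`avoided` on the correct side of the true
  monthly `D`, or `neutral` while |true D| < 0.2 — a neutral verdict at a
  truly weak selectivity is the right answer, not an error. With
  occupancy ≈ 0.3 against availability 0.225 the weak morph's true `D`
  hovers near +0.1, so sign-matching without a neutrality band would be a
  coin flip; the band states what "matching" can honestly mean there.
* activity — 6 fish per morph over 360 days, net speed scales 0.069 vs
  0.047 BLs⁻¹; the annual mean-of-monthly-means ratio and a 999-draw
  permutation test. Twelve fish keep the permutation granularity fine
  enough for p ≤ 0.01 while staying within a minute of simulation.
* home range — 5 fish per morph over six months, waypoints confined to
  home discs with a 2:1 area ratio; recovery as the mean K50 ratio.

These sizes are the package's chosen simulation design: large enough for
the contrasts to be decisive, small enough that the whole suite runs in a
few minutes on one CPU.

## Known limitations

* Jacobs `D` with two zones only; no Manly/Ivlev alternatives, no
  resource-selection regression.
* Kernel UD only (no Brownian-bridge or autocorrelated-KDE estimators),
  single bandwidth, no least-squares cross-validation.
* The permutation test replaces, but does not reproduce, a mixed model:
  no random-effect variance components, no month × morph interaction
  inference.
* Printed field values for home-range hectares depend on an unpublished
  kernel configuration and are treated as programmed contrasts in
  recovery experiments, not as reproduction targets.
* The solar routine uses the standard refraction constant; minute-level
  agreement with almanac tables is not attempted, and the polar-interval
  check allows ±3 days accordingly.
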