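# lakemorph

Annual lake-telemetry analysis of sympatric fish ecomorphs.

High-latitude lakes often hold discrete intraspecific phenotypes — for
Arctic charr (*Salvelinus alpinus*), typically a robust littoral-feeding
morph and a slim pelagic zooplanktivore. Testing whether such ecomorphs
actually *behave* differently over a full annual cycle requires tracking
individual fish through polar day, polar night and months of ice cover,
then turning hundreds of thousands of acoustic-positioning fixes into
comparable per-fish, per-month quantities. `lakemorph` implements that
workflow end to end for whole-lake positioning studies, and pairs it with
parametric generators (bathymetry, phenotype-specific trajectories, the
acoustic observation process) so that every estimator can be checked
against known ground truth.

The pipeline:

1. **Position QC** — three pre-treatment filters applied in order: logger
   geometry quality (`err <= err_max`), fix inside the lake boundary
   (boundary-inclusive), and tag-depth vs bathymetric-depth concordance.
   Each fix is excluded once, at its first failing filter; the headline
   exclusion percentage is expressed relative to the retained count.
2. **Habitat selectivity** — the littoral zone is lake area with total
   depth ≤ 8 m; per fish-month use proportions *r* are compared with the
   zone's areal availability *p* through Jacobs' index

   *D* = (*r* − *p*) / (*r* + *p* − 2*rp*),  −1 ≤ *D* ≤ 1,

   and each morph-month is given a neutrality verdict from the 95 % *t*
   confidence interval of the individual fish *D* values (preferred when
   the CI lies above 0, avoided when below).
3. **Home ranges** — per fish-month, a time-stratified subsample of 54
   positions (diel category × 3-hour block, largest-remainder quotas),
   a bivariate Gaussian kernel utilization distribution with the reference
   bandwidth *h* = σ̂ · n^(−1/6), K50/K95 isopleth areas by
   cumulative-mass cell ranking, clipped to the feasible lake boundary.
4. **Movement metrics** — displacement between consecutive fixes in body
   lengths per second (BLs⁻¹), fish depth, and distance from the lake bed,
   summarised as individual daily means, then morph-level means of monthly
   means; a label-permutation test substitutes for a mixed-model morph
   effect.
5. **Morphometrics** — nine linear traits size-corrected by regression on
   fork length, stepwise forward discriminant analysis minimising Wilks'
   Λ, canonical functions from the between/within generalized
   eigenproblem, equal-prior classification with leave-one-out validation,
   and stable-isotope (δ¹³C, δ¹⁵N) niche summaries per group.
6. **Chronobiology** — NOAA solar-position sunrise/sunset with polar-day /
   polar-night flagging at the study latitude (74.5° N), supplying the
   diel strata for the home-range subsampling.

## Worked example

```r
library(lakemorph)

lake <- make_lake(lake_spec(cell_size = 10, rng_seed = 2009))
print(lake$bathy)
#> bathy_grid: 102 x 102 cells of 10 m, 7102 wet, max depth 33.70 m

cohort <- simulate_cohort(
  lake,
  list(phenotype_spec("Littoral", littoral_affinity = 0.45,
                      step_speed_mean = 0.047, depth_target = 10.5,
                      fork_length = 440),
       phenotype_spec("Pelagic", littoral_affinity = 0.12,
                      step_speed_mean = 0.069, depth_target = 14,
                      fork_length = 265)),
  n_per_morph = c(4, 4),
  start = as.POSIXct("2009-09-01", tz = "UTC"), days = 60, seed = 2009)

qc <- run_qc(cohort$fixes, lake$polygon, lake$bathy, pipeline_config())
print(qc$report)
#> QC: 7846 in, 341 excluded (geometry 84, outside 56, depth 201),
#>     7505 valid (4.54% excluded over valid)

use  <- monthly_use(qc$valid, lake$bathy)
avail <- zone_availability(lake$bathy)
round(avail, 3)
#> p_littoral p_offshore
#>      0.225      0.775

morph_map <- setNames(cohort$fish$phenotype, cohort$fish$fish_id)
jac <- morph_monthly_selectivity(use, morph_map, avail[["p_offshore"]],
                                 habitat = "offshore")
jac[jac$month == "2009-09", ]
#>      morph   month n_fish mean_D ci_low ci_high   verdict
#>   Littoral 2009-09      4 -0.355 -0.528  -0.182   avoided
#>    Pelagic 2009-09      4  0.433  0.312   0.554 preferred
```

The synthetic lake realises the 22.5 % littoral / 77.5 % offshore split;
the morph programmed to relocate into the littoral zone 45 % of the time
comes out avoiding the offshore habitat (D < 0), while the
offshore-biased morph prefers it — the verdicts recover the programmed
contrast with fish as the replicate.

The `analysis/` directory holds six numbered drivers
(`01_simulate.R` … `06_morphometrics.R`) that run the same workflow as an
annual study (12 fish, 360 days, ice period included) and write their
tables under `results/analysis/`.

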