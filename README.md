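# pisacalc

Periodontal inflamed surface area (PISA) from full-mouth probing charts,
under two formula systems, with the simulation and cohort analyses that
compare them.

## The problem

Periodontitis is usually charted as probing pocket depths (PPD, mm) and
bleeding-on-probing flags (BOP, 0/1) at six sites around every tooth. PISA
condenses a full-mouth chart into a single continuous quantity — the surface
area, in mm², of bleeding pocket epithelium — which tracks inflammatory
burden and correlates with systemic markers such as BMI and HbA1c. For each
tooth:

- **PESA** (periodontal epithelial surface area):
  - *Japanese version*: `PESA = slope × mean PPD`, one slope per tooth type,
    derived from attachment-level measurements on extracted teeth of
    Japanese patients (accounting for racial differences in root
    morphology);
  - *original version*: `PESA = a₁x + a₂x² + … + a₆x⁶` with `x` the mean PPD
    and one coefficient set per tooth type.
- **PISA** = PESA × (fraction of the tooth's sites that bleed).
- Whole-mouth PESA/PISA are sums over teeth. Third molars are excluded
  unless the user registers coefficients for them.

The package is aimed at dental epidemiologists and clinical researchers who
want the spreadsheet calculation as scriptable, validated code: scoring
charts, comparing the two versions, and stress-testing the comparison on
synthetic cohorts.

Note on the shipped coefficient table: one printed coefficient (maxillary
lateral incisor, 5th-order original-version term) carries a misplaced
decimal point in the published table; the package stores the corrected value
0.00589, which reproduces all published totals and curves. See the methods
vignette.

## Worked example

Two maxillary central incisors probed at 5 mm on all six sites; tooth 11
bleeds at 2 of 6 sites, tooth 21 at all 6:

```r
library(pisacalc)

chart <- uniform_chart(5)[1:2, ]   # teeth 11 and 21, all sites 5 mm, all BOP+
chart$bop_b[1] <- 0; chart$bop_db[1] <- 0; chart$bop_dl[1] <- 0; chart$bop_l[1] <- 0

chart_areas(chart, version = "both") |>
  dplyr::select(tooth, tooth_class, mean_ppd, bop_frac, version, pesa, pisa)
#> # A tibble: 4 × 7
#>   tooth tooth_class     mean_ppd bop_frac version   pesa  pisa
#>   <int> <chr>              <dbl>    <dbl> <chr>    <dbl> <dbl>
#> 1    11 central_incisor        5    0.333 japanese  84.8  28.3
#> 2    21 central_incisor        5    1     japanese  84.8  84.8
#> 3    11 central_incisor        5    0.333 original  88.9  29.6
#> 4    21 central_incisor        5    1     original  88.9  88.9
```

`84.8 = 16.96 × 5` is the Japanese-version PESA of a maxillary central
incisor at 5 mm; the original polynomial gives 88.9 mm² for the same tooth.
Weighting by the bleeding fraction (2/6 and 6/6) gives each tooth's PISA;
`chart_totals()` sums them per subject and version.

The uniform-depth comparison of the two versions (28 teeth, every site
bleeding, depths 1–10 mm):

```r
sw <- pisa_sweep()
crossover(sw)       # Japanese > original below, < above: crosses in (5, 6) mm
version_ratio(sw)   # Japanese/original total ratio per depth
ggplot2::autoplot(sw)
```

Synthetic-cohort validation (no clinical data ship with the package; the
generator emulates published cross-sectional summary statistics):

```r
cohort <- generate_cohort(cohort_config(n_subjects = 210, seed = 1))
report <- run_phase3(cohort)   # paired Wilcoxon, Spearman vs BMI, adjusted OLS
generics::tidy(report)
```

A command-line interface wrapping the same functions is installed at
`inst/cli/pisa` (subcommands `calc`, `simulate`, `synth`, `phase3`).

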