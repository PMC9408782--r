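---
title: "Methods: PISA scoring, version comparison, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PISA scoring, version comparison, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisacalc)
```

## The scoring model

A full-mouth chart records, for each present tooth (FDI code), six probing
pocket depths (PPD, mm) and six bleeding-on-probing flags (BOP, 0/1) at the
sites mesiobuccal, buccal, distobuccal, distolingual, lingual,
mesiolingual. Scoring proceeds per individual tooth, never pooled across
mirror teeth:

1. mean PPD = arithmetic mean of the measured sites;
2. PESA (mm²) from the tooth type's formula —
   Japanese version `slope × meanPPD`, original version
   `a₁x + a₂x² + … + a₆x⁶`;
3. PISA = PESA × (BOP-positive sites / sites with a BOP flag);
4. whole-mouth PESA and PISA are sums over teeth.

Both formula families pass through the origin (a tooth probed at 0 mm has
no pocket epithelium), so `PESA(0) = 0` holds identically and the Japanese
version is exactly homogeneous in depth. The version is an explicit argument
everywhere; nothing defaults silently to one formula system.

**Missing sites.** Charts from partial examinations are common, but how
partially charted teeth were handled in the source data is not stated
anywhere we could anchor to. Our convention: means and bleeding fractions
use measured sites only (the denominator is the number of measured sites),
a site without a depth cannot carry a BOP flag, and a tooth with no measured
site must be omitted rather than charted empty. This matches the
"proportion of sites" definition of PISA and degrades gracefully from six
sites down to one.

**Third molars.** The shipped coefficient table covers the 14 non-third-molar
tooth types; third-molar coefficients are published elsewhere and can be
supplied via `register_third_molar_coefficients()` (both jaws at once — a
half-registered dentition is refused). The default policy excludes
position-8 teeth and reports them as skipped.

## The coefficient table and one documented correction

Coefficients are stored as exact decimal literals and guarded by a checksum
test (the 14 Japanese slopes sum to 313.26 mm²/mm), so a transcription slip
fails loudly rather than shifting totals quietly.

One printed value required judgement. The maxillary lateral incisor's
original-version fifth-order coefficient appears in the published table as
0.05890. Taken literally it drives that single tooth's PESA to ≈5460 mm² at
10 mm — an order of magnitude above every neighbouring tooth and far above
any anatomical root surface area — and it contradicts the published results
themselves: the whole-mouth original-version total at 3 mm would come out
1641.8 instead of the published 1616.1, the version crossover would move to
the 4–5 mm bracket instead of the published 5–6 mm, and the lateral
incisor's curves would not be "similar between versions" as described.
Shifting the decimal point one place (0.00589) restores every one of those
published results. The package therefore stores 0.00589; this is the only
departure from the table as printed.

A related residual is visible at deep pockets: the printed coefficients
carry five decimals (seven for the sixth-order terms), and at 8 mm the
accumulated rounding across 28 teeth amounts to a few mm². Recomputing the
original-version whole-mouth total at 8 mm from the printed table gives
5386.9 mm² against a published 5382.8 mm² (0.07%); the published value was
evidently computed from full-precision spreadsheet coefficients that were
never printed. We report what the printed table produces rather than
reverse-engineering unprinted digits.

## Numerical choices

- All computation is done in full double precision; only display and CSV
  export round, to the printed 1-decimal mm² precision, using
  round-half-away-from-zero (`round_half_up()`), since base R's
  round-half-even does not match published tables.
- The degree-6 polynomials are evaluated in Horner form; a term-by-term
  evaluation serves as the oracle in tests (agreement ≤ 1e-9 relative).
- Depths above 10 mm are outside the range on which the formulas are
  evidenced. They are computed (the polynomials are defined everywhere) but
  flagged: a warning from `pesa_area()` and an `extrapolated` column from
  `chart_areas()`. No clamping — silently altering inputs would corrupt
  sums.
- `crossover()` uses a strict sign change between consecutive grid points;
  an exact zero at a grid point flanked by opposite signs is reported as the
  degenerate interval (x, x), and an identically zero difference (both
  versions equal) is no crossover at all.
- `check_pesa_monotonicity()` scans a 0.1 mm grid on 1–10 mm. The Japanese
  slopes are positive so that version is monotone by construction; for the
  original version the scan flags a real feature of the published
  polynomials — the mandibular second molar decreases slightly on
  ≈1.2–1.4 mm. The package surfaces this rather than hiding it; no result
  in the package depends on monotonicity there.

## The uniform-depth simulation

`pisa_sweep()` evaluates both versions with every site of all 28
non-third-molar teeth at the same depth and every site bleeding (so PISA =
PESA). Per tooth type it reports one tooth; the whole-mouth total doubles
the 14-type sum. The default grid is the integers 1–10 mm (the published
design); a finer grid is available for localising the crossover more
narrowly, but the headline result is the integer bracket.

## The synthetic cohort generator

The clinical cross-sectional data behind the paired validation are not
public. The generator therefore produces a *stand-in* cohort whose marginal
summaries emulate the published subject characteristics (n = 210, 70 male /
140 female; medians and IQRs of age 70 (61–76) y, BMI 22.9 (20.4–25.0)
kg/m², 25 (21–27) teeth, subject mean PPD 2.29 (2.08–2.50) mm, BOP 13.4
(8.0–23.3)%). Every distributional family below is this package's choice —
the published report gives only the marginals, so no claim of joint-
distribution fidelity is made:

- age: normal truncated to [40, 95] y; BMI: log-normal; subject mean PPD:
  1 mm + gamma; bleeding propensity: beta. Each family's parameters are
  fitted at configuration time by least squares on the three target
  quantiles (truncated-normal quartiles cannot be exactly asymmetric, so
  age lands within ≈1 y of its targets — visible in the calibration test
  tolerances).
- tooth count: beta-binomial over the 28 non-third-molar positions
  (fitted on linearly interpolated discrete quantiles), positions dropped
  uniformly at random; third molars are never generated; a count of 0 is
  lifted to 1 because an edentulous mouth has no chart.
- site depths: subject mean + centred gamma noise (shape 2, rate 2,
  SD ≈ 0.7 mm), rounded to integer mm and clamped to [1, 10] — probing
  depths are clinically charted in whole mm, a sulcus of ≥1 mm always
  exists, and the clamp keeps every site inside the formulas' evidenced
  range.
- bleeding: per-subject beta propensity, shifted on the logit scale by
  `bmi_inflammation_effect` × standardised BMI, plus a within-mouth logit
  uplift of 0.25 per mm a site is deeper than its mouth's mean. The uplift
  encodes the clinical co-occurrence of bleeding and deeper pockets while
  leaving the cohort-level bleeding marginal essentially at its beta
  target; without it PISA would be an implausible product of independent
  factors.
- `bmi_inflammation_effect` defaults to 0.21, calibrated once at large n so
  that Spearman's rho between whole-mouth PISA and BMI is ≈0.19, the
  association strength reported for the clinical cohort. With the effect
  set to 0, PISA and BMI are independent by construction — a property the
  tests exploit.

Cohorts are deterministic functions of the config (including its seed);
identical configs regenerate byte-identical cohorts.

What passing the calibration tests does **not** show: the generator matches
five marginal summaries and one correlation, not the clinical joint
distribution, tooth-level spatial patterns, examiner error, or disease
subgroups. Consequently the paired-comparison *medians* computed on
synthetic cohorts are not expected to equal the published clinical medians;
what is tested is the mechanism and direction — with subject mean depths
around 2.3 mm the whole-mouth totals sit in the regime where the Japanese
version exceeds the original, so the synthetic paired comparison must (and
does, across seeds) reproduce the published direction and significance.

## Statistical conventions

- **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): zero differences
  dropped; midranks for tied absolute differences; exact null distribution
  when ≤25 tie-free nonzero pairs remain, otherwise normal approximation
  with tie and continuity corrections; two-sided p-values. The published
  analysis does not state its zero/tie policy or whether p-values were
  exact; these are the conventions of mainstream statistics packages, and
  tests pin them against full 2ⁿ enumeration on small samples.
- **Spearman** (`spearman_assoc()`): product-moment correlation of
  midranks; two-sided p from the t approximation (documented as an
  approximation; in small samples it is not exact).
- **Standardised regression** (`standardized_regression()`): OLS on raw
  variables; standardised betas `b·sd(x)/sd(y)` with sample SDs, applied to
  the 0/1 sex indicator as well (the convention of common packages —
  debatable for binary predictors, so raw coefficients are reported
  alongside); predictor collinearity is rejected by condition number. No
  covariates beyond age and sex are modelled, mirroring the published
  adjustment set and its acknowledged limitations (e.g. smoking is absent).
- `run_phase3()` computes both versions on identical charts and subjects,
  so the paired and association analyses are always aligned; subjects
  without teeth are dropped with a message.

## Problem sizes used by the test suite

Calibration checks run the generator at n = 5000 with tolerances fixed in
advance at roughly twice the largest deviation observed in 15 independent
generations at that size; the direction-and-significance property runs 100
cohorts of n = 210; the enumeration cross-check covers 200 random
signed-rank instances at n ≤ 12. These sizes make the whole suite complete
in well under a minute per heavy block while leaving the checks far from
their tolerance boundaries.

## Known limitations

- The CAL (clinical attachment level) + gingival recession route to PESA is
  out of scope; the implementation scores PPD-based charts only.
- Third-molar scoring requires user-supplied coefficients.
- The original-version polynomials are used as printed (5-decimal
  precision); totals at deep pockets inherit the few-mm² reconstruction
  residual described above.
- The synthetic cohort is a calibrated stand-in, not a clinical dataset;
  conclusions about real populations require real charts.
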