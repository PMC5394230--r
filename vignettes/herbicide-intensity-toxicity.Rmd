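---
title: "Measuring herbicide use intensity and relative toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring herbicide use intensity and relative toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbtrends)
```

## The two indicators

National pesticide-use surveys report, per crop and year, the total amount
of each herbicide product applied and its average application rate.
Summing raw weights across products misleads, because use rates differ by
orders of magnitude between active ingredients. `herbtrends` computes two
indicators that do not share this defect.

**Area-treatments.** For active ingredient $ai$ in a crop-year,
$$AT_{ai} = \frac{\mathrm{Amount}_{ai}}{\mathrm{Rate}_{ai}\cdot \mathrm{Area}},$$
with amount in kg, average rate in kg ha⁻¹ and planted (not harvested)
area in ha. $AT_{ai}$ is the fraction of the crop area that would be
covered at the average rate; the per-crop total $\sum_{ai} AT_{ai}$ counts
full-rate field passes and can exceed 1 — two full-rate products in a tank
mix give 2, as do four products at half rate. Totals are computed over the
surveyed years only; gaps (rice was surveyed six times in 25 years) are
never interpolated.

**Hazard quotients.** For one crop-year and endpoint,
$$HQ = \sum_{ai=1}^{N} \frac{\mathrm{Amount}_{ai}}{\mathrm{Toxicity}_{ai}},$$
with amount in mg per planted hectare (kg × 10⁶ / ha). Chronic toxicity is
the no-observable-effect level (NOEL) from 24-month oral rat studies
(mg kg⁻¹ d⁻¹) — the most consistently available chronic endpoint, and one
measured on the same species and duration for every ingredient. Acute
toxicity is the oral rat LD50 (mg kg⁻¹). $HQ$ is read as the number of
NOEL or LD50 doses applied per hectare; the per-day and per-kg-body-weight
denominators of the toxicity units are deliberately not rescaled away, so
$HQ$ is a relative index, not an exposure estimate. Endpoints are never
blended: each call computes one of `"chronic"` or `"acute"`.

The quotient is linear in amounts, so each ingredient has a well-defined
contribution share (`contribution_share()`, summing to 100%). These shares
are the main interpretive tool: a crop whose chronic HQ is 90% one
compound is one regulatory decision away from a step change.

### Assumptions and limitations

* Mammalian (rat) oral toxicity only — most relevant to applicator risk.
  Nothing here supports conclusions about aquatic, avian or pollinator
  risk, degradates, persistence or leaching.
* No mixture interactions: quotients are additive by construction.
* The average application rate is taken exactly as the survey supplies it;
  whether it is per-application or per-crop-season cannot be resolved from
  the survey and is not second-guessed.
* Amounts are assumed acid-equivalent (the NASS convention), so salt
  consolidation sums amounts with a mass factor of 1 by default; a
  per-label `mass_factor` hook exists for sources that report salt weight.

## Censored acute toxicity

Registrants need not establish LD50s above 5,000 mg kg⁻¹ (EPA Category
IV), so many acute values arrive as the string `">5,000"`.
`censor_ld50()` substitutes the bound itself and flags the record. The
substitution is conservative for hazard: since the true LD50 exceeds the
bound, the computed acute HQ is an upper bound on the contribution of any
censored ingredient (a tested property). The acute toxicity distribution
is therefore left-biased at 5,000, and acute percentile statements for
ingredients near the bound should be read with that in mind.
`toxicity_percentile()` uses strict inequality — tied values do not count
as "more toxic" — because any tie rule is arbitrary and the strict one
never overstates how extreme an ingredient is.

## Label consolidation

Surveys list formulations, not active ingredients (eight salts of 2,4-D,
seven of glyphosate). `canonicalize()` matches case-insensitively after
whitespace normalization against a user-supplied mapping; unmapped labels
pass through as themselves (logged) rather than erroring, so intensity
computations never stall on an incomplete mapping. Merged average rates
are amount-weighted means, so a dominant formulation dominates the merged
rate; the simple mean would let a rarely used ester distort the rate of a
mostly-salt ingredient. Ingredients lacking a toxicity profile stay in the
AT computation (Equation AT needs no toxicity) but are excluded from HQ
with a logged warning and a manifest count.

## Trend tests

* `mann_kendall()` — the nonparametric test for monotonic trend, on
  $S=\sum_{i<j}\operatorname{sign}(v_j-v_i)$ with tau-b (tie-corrected
  denominator), chosen because hazard series can repeat values. For
  tie-free series with $n \le 10$ the two-sided p-value is exact, from the
  full null distribution of $S$ (computed via the inversion-count
  recurrence, equivalent to enumerating all $n!$ orderings — and tested
  against literal enumeration for $n \le 7$). Above that, the conventional
  normal approximation with tie-corrected variance and continuity
  correction. The `method_note` field always says which branch ran. The
  threshold of 10 keeps the exact branch under a millisecond while
  covering the series lengths (6) where exactness matters most.
* `ols_slope()` — least-squares slope of value on calendar year, two-sided
  t-test with $n-2$ df. Calendar year is the regressor even for gappy
  series; a perfectly collinear fit reports p = 0 (or 1 for a constant
  series) with a degenerate flag rather than NaN.
* `pearson_correlation()` — sample $r$ with the t-transform p-value; used
  to ask whether chronic and acute toxicity rank ingredients similarly
  (across real herbicides, they largely do not).

Degenerate inputs are contracts, not accidents: constant series give
tau = 0, p = 1 with a flag; $n<3$, duplicate years, or constant vectors in
a correlation are errors.

## The synthetic world

`generate_survey_data()` exists so every pipeline stage can be tested
end-to-end without downloads. Amounts are *derived from target
area-treatments* (`amount = AT × rate × area`) rather than sampled, so at
`noise_sd = 0` the pipeline must recover the configured per-crop linear AT
trend, hazard quotients and contribution shares exactly — parameter
recovery is by construction, which is the point: any discrepancy is a
pipeline defect, not generator noise.

Defaults encode the stated world of the 1990–2015 US record:

| parameter | default | why |
|---|---|---|
| crops, surveyed years | six crops, 1990–2015; rice only 1990, 1992, 1995, 2000, 2006, 2013 | the real survey's coverage pattern |
| ingredients per crop | 75 / 57 / 54 / 34 / 44 / 56, from a shared pool of 118 | the published per-crop active-ingredient counts |
| AT slopes | 0.02–0.09 per year by crop | the published linear-regression slope range |
| chronic NOEL | log-uniform 0.03–20,000 mg kg⁻¹ d⁻¹ | the published chronic range |
| acute LD50 | log-uniform 112–9,000 mg kg⁻¹, `censor_prob = 0.3` mass at 5,000 | the published acute range; "many" censored values, fixed once at 0.3 |
| AT baselines | 1.0–2.5 by crop | plausible; the survey's absolute levels are not printed, only trends |
| planted areas | 1.2M ha (rice) to 35M ha (maize) | order-of-magnitude US planted areas |
| rates | log-uniform 0.02–2 kg ha⁻¹ | herbicide rates span grams to kilograms per hectare |
| dominance weights | geometric, ratio 0.6 | one or two ingredients carry most use/hazard, the atrazine/molinate pattern |
| `noise_sd` | 0.1 (multiplicative log-normal on amounts) | mild survey estimation error; 0 for exact-recovery tests |

These values were fixed once, before any acceptance measurement, and are
not tuned. `n_labels_per_ai` defaults to 1; salt multiplicity is exercised
explicitly in tests (k up to 7) because the real label-to-ingredient ratio
depends on crop mix.

Randomness is split into one stream per table and per crop
(`derive_seed()`), so adding a crop changes nothing else — a tested
determinism contract, byte-identical files included.

**What a green test establishes.** Zero-noise recovery shows the
arithmetic chain (units → consolidation → AT → HQ → trends) is exact.
It does not validate the generator against real surveys: real data have
nonresponse, state-level stratification, rate redefinitions across years
and non-linear adoption dynamics (the soybean dip-and-rise) that the
generator deliberately does not model. Reproduction of the published
numbers therefore remains a separate acceptance criterion that requires
the survey's own supplementary files and stays red without them.

## Numerical choices

* Conversions are fixed at 1 lb = 0.45359237 kg, 1 acre = 0.40468564224 ha,
  applied once at read time; all downstream math is metric.
* Contribution shares must sum to 100 within 1e-9; the share denominator
  is the freshly summed quotient, so this is a genuine consistency check,
  not an identity.
* Zero-noise "exact" recovery is asserted at 1e-12 relative tolerance —
  double-precision exactness across a sum of ~100 products.
* Output tables are written with fixed (crop, year, ai) ordering so reruns
  are byte-identical and diffs are meaningful.
* Percent change in summaries uses first and last *surveyed* years, not
  regression endpoints; single-year series report change as not
  applicable.

## Known limitations

Beyond the scope limits above: no Sen's slope or autocorrelation-adjusted
trend tests (series are short and annual); no changepoint modeling, so a
dip-and-rise pattern can yield a non-significant monotonic trend that
hides real structure; the EIQ composite index is deliberately absent —
its toxicity scaling produces incoherent rankings, which is part of why
the hazard-quotient approach is used here.
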