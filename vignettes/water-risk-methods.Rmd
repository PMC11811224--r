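---
title: "Methods: non-carcinogenic risk assessment for drinking-water contaminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-carcinogenic risk assessment for drinking-water contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watrisk)
library(dplyr)
```

## The model

watrisk implements the standard chronic-ingestion exposure model for
non-carcinogenic risk from drinking water. For a contaminant at
concentration $C$ (mg/L) and a receptor described by ingestion rate $IR$
(L/day), exposure frequency $EF$ (days/year), exposure duration $ED$
(years), body weight $BW$ (kg) and averaging time $AT$ (days), the
estimated daily intake is

$$EDI = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}
\quad \text{(mg/kg/day)},$$

the hazard quotient is $HQ = EDI / RfD$ with $RfD$ the chronic oral
reference dose, and the hazard index over co-occurring contaminants is
$HI = \sum_i HQ_i$. $HQ > 1$ (and $HI > 1$) flags potential
non-carcinogenic concern; it is a screening threshold, not a dose-response
prediction.

The packaged data are a 22-brand bottled-water survey measuring fluoride
(RfD 0.06 mg/kg/day, WHO guideline 0.5–1.5 mg/L) and nitrate
(RfD 1.6 mg/kg/day, WHO upper guideline 45 mg/L), with four exposure
profiles:

```{r}
load_fixture("exposure_table1")
```

For all four profiles $AT = ED \times EF$, so EDI reduces exactly to
$C \cdot IR / BW$; the `at_consistent` flag records this. The ratio
$IR/BW$ (0.093, 0.053, 0.040, 0.035 L/kg/day) fixes the ordering
infants > children > teenagers > adults for any concentration —
body weight, not intake volume, drives the infant excess.

## Deterministic engine

`risk_table()` computes one EDI/HQ cell per brand × group × contaminant
and one HI per brand × group. HI pairs hazard quotients **by brand
identifier, never by row position**: a hazard index is only meaningful for
the same bottle of water. In the source survey's printed per-brand HQ
table the nitrate column is shifted by one row relative to the brand
order (the fluoride column confirms row order is brand order), so
per-brand HIs computed here differ from what one would read off that
table; column means are unaffected. One consequence is worth knowing:
with correct pairing, three brands — not two — exceed HI 1 for infants
(B3, B15, and B6, whose fluoride 0.49 and nitrate 4.28 mg/L combine to
HI 1.01).

```{r}
rt <- risk_table(
  list(fluoride = load_fixture("fluoride_table2"),
       nitrate  = load_fixture("nitrate_table2")),
  load_fixture("exposure_table1")
)
filter(rt$hi, group == "infants", hi > 1)
```

Exceedance counts use strict `> 1`. Report files round to 2 decimals with
halves rounding up, matching the survey's printing; all internal
computation is full precision. The sample SD uses the $n-1$ denominator
and is reported as `NA` (not 0) for a single record, where it is
undefined.

## Uncertainty propagation

`simulate_hq()` propagates parameter uncertainty by Monte Carlo:
per trial, $C$, $IR$ and $BW$ are drawn independently from configurable
marginals and the HQ recomputed; $EF$, $ED$, $AT$ and $RfD$ stay fixed.
The default marginals, all overridable through `scenario_spec()`:

* **Concentration** — lognormal, fitted to the panel's measured values by
  log moments (`fit_lognormal()`: `p1` = mean of natural logs, `p2` =
  sample SD of logs). Values below a detection floor (default
  0.005 mg/L) are clamped up before logging, the detection-limit
  convention that keeps a single near-zero reading from dominating the
  log scale; the clamp count is reported.
* **Ingestion rate** — lognormal with median equal to the profile's IR
  and log-SD 0.25, a conventional spread for consumption-rate
  uncertainty that keeps the central estimate at the tabulated value.
* **Body weight** — normal with mean at the profile's BW and coefficient
  of variation 0.15, truncated below at 20% of the mean so the divisor
  stays physical.

Truncation is enforced by rejection (redraw out-of-bounds values, bounds
inclusive); an interval capturing less than 0.01% of a probe batch
errors out rather than looping. Trials default to 10,000. Percentiles
use linear interpolation at rank $1 + (n-1)q$ (the type-7 convention),
so summaries are a fixed, documented function of the order statistics.

Reproducibility uses one root seed per scenario; per-variable streams are
derived from it by hashing the variable name, group and (for
concentration) contaminant. Because the IR and BW streams do not depend
on the contaminant, `simulate_hi()` gets shared ingestion-rate and
body-weight draws across contaminants within a trial — one simulated
person per trial — while concentrations stay independent. The HI trial
vector is exactly the elementwise sum of the per-contaminant HQ vectors.

The survey this package reimplements reports 95th-percentile HQs from a
commercial Monte Carlo tool without stating its distribution parameters;
those printed percentiles are internally inconsistent with the
deterministic means (the infants' mean fluoride HQ, 0.50, exceeds the
reported 95th percentile, 0.18) and are therefore not reproduced here.
The probabilistic engine is instead validated by properties: point-mass
collapse to the deterministic value, agreement of the simulated mean
with the analytic independence factorisation
$E[C]\,E[IR]\,E[1/BW]/RfD$, percentile monotonicity, seed determinism,
and parameter recovery of the lognormal fit.

## Sensitivity analysis

`sensitivity_report()` ranks inputs by contribution to variance, defined
as the normalised squared Spearman rank correlation between each input's
trial values and the output:
$100\,\rho_i^2 / \sum_j \rho_j^2$. This is the convention of the
commercial risk tools used in exposure assessment; it is rank-based, so
contributions are invariant to monotone rescaling of any input.
Body weight enters the dose inversely; its rank correlation is negative
and is reported signed, while the contribution uses the square.
Zero-variance (point) inputs are flagged degenerate and contribute 0.
Full-precision contributions sum to 100 up to floating point; the
1-decimal display column is reconciled to sum to exactly 100 by the
largest-remainder method. Under the default scenarios the concentration
dominates (about 90% for the fluoride panel) in every age group,
consistent with the survey's qualitative finding.

```{r}
infants <- filter(load_fixture("exposure_table1"), group == "infants")
sc <- default_scenario(load_fixture("fluoride_table2"), infants,
                       n_trials = 5000, seed = 7)
sensitivity_report(sc)
```

## Synthetic panels

`generate_panel()` draws brand panels with known ground truth so every
stage is testable without external data: lognormal brand means (defaults
`p1 = -1.3`, `p2 = 0.85`, 22 brands — the right-skewed shape and scale of
the packaged fluoride panel), censoring at the detection floor, 5%
relative replicate noise, labels missing with probability 8/22 and
otherwise scattered around the measurement by a lognormal(0, 0.2)
factor, emulating label/measurement discrepancy. What it deliberately
does not emulate: correlation between brands, between contaminants
within a brand, temporal drift, or non-lognormal concentration shapes —
so passing tests certify the pipeline's arithmetic and contracts, not
distributional realism of any particular real survey.

## Numerical and design choices

* Label cells printed as bounds (`"< 2"`) are stored verbatim in
  `label_note` and never parsed as numbers; "NL"/empty means unlabeled.
* Guideline screening assigns exactly one of `below_low` / `within` /
  `above_high` per brand (bounds inclusive on `within`); the unlabeled
  flag is independent.
* The published nitrate summary SD (1.41) recomputes to 1.40 from the
  printed concentrations; the difference is display rounding in the
  source, and the packaged values reproduce 1.40.
* Test and vignette simulations use 2,000–20,000 trials; the analytic
  factorisation check uses 100,000, where the Monte Carlo standard error
  is small enough for a 3-SE test to be meaningful. These sizes are the
  package's chosen balance of sharpness against runtime.
* Errors are classed conditions (`watrisk_validation_error`,
  `watrisk_schema_error`, ...) so pipeline callers can branch on failure
  kind.

## Limitations

Only the ingestion route is modelled — no dermal or inhalation exposure,
no carcinogenic slope factors, no cumulative intake from food or other
water sources, and no unit handling beyond mg/L and mg/kg/day. The
hazard quotient is a screening ratio; values near 1 warrant measurement,
not alarm.
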