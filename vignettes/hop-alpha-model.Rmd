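---
title: "Predicting hop alpha-acid content from window accumulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hop alpha-acid content from window accumulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopalpha)
```

## The model

Alpha-acid accumulation in hop cones integrates a season's heat and water
supply between two phenological anchors: second germination after spring
pruning (F3) and technological maturity of the cones (F9). `hopalpha`
evaluates the empirical rational-polynomial model

$$\alpha \;=\; \frac{k_2 + k_3 w^2 - k_1 w}{10\,x},$$

where $x$ is the effective temperature sum and $w$ the rainfall sum, both
over the closed window $[F3, F9]$, and $\alpha$ is the alpha-acid content in
percent of cone dry matter. For cv. Aurora the coefficients are
$k_1 = 53.8$, $k_2 = 453$, $k_3 = 1.33$; the packaged registry ships this
entry, and `fit_coefficients()` calibrates the triple for other cultivars.

The form has two features worth keeping in mind. It was obtained by
symbolic regression on assayed seasons, and the raw regression output (the
fraction $(k_1 w - k_2 - k_3 w^2)/x$, available as `alpha_raw()`) is
negative and an order of magnitude too large; the usable prediction divides
it by $-10$, and the package keeps that relation exact by construction.
Second, the model is purely empirical: the coefficients carry the units
needed to balance (degree-day, mm, %) scales and have no mechanistic
reading.

### The two accumulations

The effective temperature sum uses the daily midpoint above a 5 °C base,
the minimal temperature for hop vegetation:

$$x = \sum_{d \in [F3,F9]} \left(\frac{T_{min,d}+T_{max,d}}{2} - 5\right).$$

As written the sum keeps negative daily terms, and that literal form is the
package default. Degree-day practice often clamps negative terms to zero;
`clamp_negative = TRUE` does so. Over realistic F3–F9 windows (May–August)
daily means below 5 °C are rare, so the two conventions usually coincide;
which one produced the published sums cannot be settled from the published
record, and the choice is exposed rather than hidden.

Both accumulations run over the *closed* interval — both endpoint days
contribute. "From F3 to F9" without further qualification is read in the
common agronomic way. Missing calendar days inside the window are an error,
never silently skipped: a gapped sum is biased low, which for this model
inflates the prediction.

### The drought gate

The model's validity is gated on mean July reference crop
evapotranspiration (ET0, mm/day): above 4.5 mm/day the season is flagged
*not reliable*. Extreme drought disturbs the formation and development of
the glandular trichomes where alpha-acids accumulate, an effect the
temperature and rainfall sums cannot represent. Design choices around the
gate:

* the boundary value 4.5 itself is reliable (the constraint is
  $ET_0 \le 4.5$);
* the gate is an annotation, not a domain restriction — a gated-out season
  still gets its computed value, flagged, because the number is useful for
  diagnosing *how* the model fails in drought;
* when the weather table carries no ET0 column, prediction proceeds with a
  warning reason instead of refusing: the gate cannot be assessed, and that
  is recorded in the prediction's `reason` field.

July is aggregated as the arithmetic mean of the 31 daily ET0 values
(mm/day), all of which must be present. ET0 itself is an input; the package
does not compute it from radiation, wind or humidity.

### Reporting precision

Predictions are reported at one decimal, *truncated toward zero*
(10.917 → 10.9), with the full-precision value always retained alongside.
Truncation, not rounding, is the convention that matches the published
reference record across all six reliable seasons; round-half-up would
disagree on three of them. A guard rounding at the ninth decimal absorbs
floating-point dust before truncating, so values such as
`9.3 - 1e-12` report as 9.3.

## The reference seasons and a known discrepancy

The package ships seven assayed Aurora seasons (six from Gregurovec,
Croatia, 2001–2006, one from Žalec, Slovenia, 2012) with their window sums,
July ET0, published calculated values and laboratory assays
(`aurora_seasons()`). `reproduce_reference_table()` recomputes the table:

```{r}
cat(format_validation_table(reproduce_reference_table()), sep = "\n")
```

All six reliable seasons reproduce their published calculated value exactly
at reporting precision. The 2003 drought season does not: the model yields
about 1.6 on its printed inputs where the published table shows 2.5. The
season is gated out (July ET0 5.5 > 4.5) in both accounts, so the
discrepancy has no bearing on the model's validated surface; the package
annotates it rather than forcing agreement.

One more reporting subtlety: the published difference for 2005 (0.5)
matches the *unrounded* calculated value minus the assay (10.156 − 9.7),
not the truncated one (10.1 − 9.7 = 0.4). The validation table therefore
carries both `difference` (on the reported scale, used for classification)
and `difference_unrounded`.

## Validation against assay tolerances

The laboratory reference is the lead conductance assay (EBC 7.4), whose own
tolerance borders define what prediction-assay agreement can mean:
repeatability r95 = 0.2 and reproducibility R95 = 1 (% d.m.). A prediction
within r95 of the assay is indistinguishable from a within-laboratory
repeat; within R95, from a between-laboratory repeat. `validate_seasons()`
classifies each season's signed difference (calculated − assayed) by its
magnitude into `within_repeatability`, `within_reproducibility` or
`outside_tolerance`, with `not_reliable` overriding when the gate fails.
Differences are stored signed but classified on magnitude; a 1e-9 epsilon
absorbs subtraction dust on the 0.1-quantized reported scale, so a
difference of exactly 0.2 classifies as repeatable.

Across the six reliable reference seasons the absolute differences span
0.1–0.7 % d.m., all within the reproducibility border.

## Calibration for other cultivars

Multiplying the model by $10x$ makes it linear in the coefficients:

$$10\,x\,\alpha = k_2 + k_3 w^2 - k_1 w.$$

`fit_coefficients()` therefore solves ordinary least squares on the
transformed response $z = 10x\alpha$ with design columns $(1, -w, w^2)$ —
exact, closed-form and order-invariant. The transformation implicitly
weights alpha-scale residuals by $x$; since $x$ varies only ~±10% across
realistic seasons the distortion is mild, and `method = "alpha"` offers a
direct numerical minimization of the untransformed squared error
(Nelder-Mead started at the OLS solution) for comparison.

Practical notes:

* at least three usable observations are required (three unknowns), and the
  design must not be rank-deficient — seasons sharing a single rainfall sum
  cannot separate $k_1$, $k_2$, $k_3$;
* gated-out (drought) seasons are excluded by default
  (`use_unreliable = TRUE` overrides), since they lie outside the model's
  validity domain;
* no regularization is applied; with few seasons the design is very
  ill-conditioned (columns $1$, $w$, $w^2$ over a narrow rainfall range),
  so the result carries `condition_diagnostic`, the exact condition number
  of the design matrix. Refitting on the six reference seasons yields
  coefficients far from the registry triple yet with *smaller* residuals —
  with $n = 6$ and a condition number around $10^8$ the coefficients are
  individually unidentifiable even though the fitted surface is stable over
  the observed $(x, w)$ range. Refit coefficients should be read as a
  package, not term by term.

```{r}
fit <- fit_coefficients(aurora_obs <- within(aurora_seasons(), {
  x <- x_eff_temp_sum; w <- w_rain_sum
  reliable <- et0_july_mean <= 4.5
})[, c("x", "w", "alpha_assay_pct", "reliable")])
fit
```

## The synthetic-season generator

No raw daily station records are published for the reference seasons, so
the generator `synth_season()` manufactures daily series whose window
accumulations hit prescribed targets exactly: it is first-class,
deterministic (given a seed) code, used by the tests, the worked examples
and the acceptance script.

Allocation choices: each day's mean temperature is the 5 °C base plus the
constant excess `target_x / n_days`, perturbed by a seeded zero-sum jitter
whose amplitude is capped at the mean excess (rescaled after centering), so
no daily excess goes negative — hence clamped and unclamped degree-day sums
agree, and the target is recovered under either convention. The min/max
pair sits symmetrically around the mean (3–6 °C half-range), exploiting
that the degree-day sum depends only on the midpoint. Rain falls as a
uniform 0.1 mm-quantized daily amount with the remainder on the final day.
July days get the requested ET0 value exactly; other days a nuisance value
near 3.5 mm/day.

What the generator does *not* emulate: autocorrelated synoptic weather, wet
/dry spell structure, seasonal temperature trends, or any coupling between
rain, temperature and ET0. Tests passing on synthetic seasons therefore
demonstrate the correctness of the accumulation-to-prediction pipeline and
the exactness of the algebra — not that the model generalizes to new
seasons, which only assayed field data can show.

## Numerical choices and degenerate inputs

* Window sums are plain floating-point sums in date order; at season scale
  (~120 terms) this is accurate to ~1e-13 relative.
* `predict_alpha()` requires $x > 0$ (the model divides by $x$) and
  $w \ge 0$; non-finite inputs are rejected.
* Prediction scales exactly as $1/x$ at fixed $w$, a property the tests
  exercise, and `alpha_raw()` relates to the prediction by exactly $-10$
  by construction.
* Weather CSVs are written with 17 significant digits so a write/read
  round trip is lossless.
* A comma-decimal CSV dialect is accepted behind `dec = ","` for regional
  station exports.

## Problem sizes

Examples, tests and the acceptance script run on 120-day windows (a
realistic F3–F9 span), seven reference seasons, and calibration designs of
3–20 seasons; everything completes in seconds on one core.

## Limitations

The model is calibrated for cv. Aurora in two central-European growing
regions; the coefficients, the 5 °C base and the 4.5 mm/day gate are not
transferable claims. It consumes ET0 rather than computing it, treats the
phenology dates as inputs (no phenological model), and offers no
uncertainty quantification beyond residual diagnostics — with six
calibration seasons, honest interval estimates are out of reach.
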