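# hopalpha

Alpha-acids are the humulone-family bittering compounds of hop
(*Humulus lupulus* L.) cones, assayed as a percentage of cone dry matter,
and their expected level drives pricing and harvest decisions in the hop
trade. `hopalpha` implements an empirical agrometeorological model that
predicts the alpha-acid content of cv. Aurora before the laboratory assay is
available, using only two accumulations over the phenological window from
second germination after spring pruning (stage F3) to technological maturity
of the cones (stage F9):

```
        k2 + k3 w^2 - k1 w
alpha = ------------------            valid when ET0(July) <= 4.5 mm/day
              10 x
```

where

* `x` — effective temperature sum (degree-days above a 5 °C base, the
  minimal temperature for hop vegetation), computed from daily minimum and
  maximum temperatures as `sum((Tmin + Tmax)/2 − 5)` over F3…F9;
* `w` — rainfall sum (mm) over the same window;
* `k1, k2, k3` — cultivar coefficients, `(53.8, 453, 1.33)` for Aurora;
* the prediction is reported at one decimal, truncated toward zero.

The model is not trusted in extreme drought: when mean July reference crop
evapotranspiration (ET0) exceeds 4.5 mm/day, glandular trichome formation is
disturbed in ways the two accumulations cannot capture, and the prediction
is flagged *not reliable* rather than suppressed.

The package is aimed at agronomists and hop-industry analysts: it reads
daily weather-station CSVs, extracts the phenological window, computes the
accumulations, evaluates the gated prediction, validates predictions against
assay values using the EBC 7.4 tolerance borders (repeatability r95 = 0.2,
reproducibility R95 = 1 % d.m.), and recalibrates the three coefficients for
other cultivars by linear least squares. A deterministic synthetic-season
generator produces daily series hitting prescribed accumulation targets for
testing and demonstration.

## Worked example

```r
library(hopalpha)

# A season whose window sums match the 2001 Gregurovec record
window <- phenology_window("2001-05-03", "2001-08-30")
series <- synth_season(target_x = 1698.4, target_w = 393.7, window,
                       et0_july_mean = 4.26, seed = 7)
summary <- summarize_season(series, window)
predict_season(summary, hop_cultivar("Aurora"))
#> <prediction_record> Aurora 2001: alpha = 10.9% d.m. (full 10.9174) [reliable]
#>   July ET0 4.26 <= 4.50 mm/day
```

The reported 10.9 % d.m. is the one-decimal truncation of the full-precision
prediction 10.917; the season passes the drought gate because mean July ET0
(4.26 mm/day) is below the 4.5 mm/day threshold. The packaged validation
table recomputes all seven reference seasons (six reliable, plus the 2003
drought season which gates out):

```r
cat(format_validation_table(reproduce_reference_table()), sep = "\n")
#>  year      x     w ET0_Jul calc assay diff                  class
#>  2001 1698.4 393.7    4.26 10.9  11.6 -0.7 within_reproducibility
#>  2002 1932.1 425.8    4.20 11.3  11.1 +0.2   within_repeatability
#>  2003 1994.4 175.2    5.50  1.5   6.7 -5.2                    n/r
#>  2004 1856.7 398.5    4.28 10.2  10.0 +0.2   within_repeatability
#>  2005 1920.8 403.3    4.38 10.1   9.7 +0.4 within_reproducibility
#>  2006 1872.1 382.0    4.42  9.2   9.3 -0.1   within_repeatability
#>  2012 1766.2 400.4    4.20 10.8  10.2 +0.6 within_reproducibility
```

Every reliable season's calculated value differs from the laboratory assay
by at most 0.7 % d.m., within the between-laboratory reproducibility border
of the assay itself.

Coefficients for another cultivar are fitted from assayed seasons with
`fit_coefficients()`, which exploits that the model is linear in
`(k1, k2, k3)` after multiplying through by `10x`.

## Command-line interface

A thin wrapper `exec/hopalpha` exposes the package as
`hopalpha {predict|summarize|fit|validate|tables|simulate}`; run it with no
arguments for usage. For example:

```sh
hopalpha simulate --target-x 1698.4 --target-w 393.7 \
  --f3 2001-05-03 --f9 2001-08-30 --et0-july 4.26 --seed 1 --out weather.csv
hopalpha predict --weather weather.csv --phenology phenology.json
```

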