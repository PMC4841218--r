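# cosinorsel

Cosinor analysis of time-of-day effects with selection-effect benchmarks.

## The problem

Online studies that are open around the clock produce outcomes that can be
plotted against time of day, and those plots often show a wave. A wave can
mean a **circadian rhythm** (the outcome truly oscillates within person over
the 24-hour day) or a **selection effect** (different people participate at
different clock times, and those people differ in the outcome — the sample's
composition oscillates, nobody's score does). `cosinorsel` is for analysts
of large cross-sectional time-stamped datasets — online demonstration
studies, social-media-derived measures, crowd-sourced experiments — who need
to decide which interpretation the data support.

## The method

The core model is the single-component 24-hour **cosinor**: least squares of
the (covariate-residualized) outcome on sin(2πt/24) and cos(2πt/24), giving

- mesor *M* (midline), amplitude *A* = √(β²ₛ + β²꜀),
- acrophase φ = (24/2π)·atan2(βₛ, β꜀) mod 24 — the clock time of the peak,
- variance explained r² (%) and the joint F test of the two trigonometric
  coefficients, F(2, n−3).

Around it, the pipeline implements:

1. **Residualized rhythm fitting** — demographics are dummy-coded and
   regressed out (with linear + quadratic study-day detrending) before the
   cosinor; the rhythm is fit to residuals.
2. **Phase-moderation tests** — sine×moderator and cosine×moderator
   interaction pairs, tested jointly, for daylight saving time, gender, and
   age; plus a per-year-of-age acrophase curve with a weighted linear
   summary (minutes of acrophase shift per year of age).
3. **Selection benchmarks** — the same cosinor fit to *fixed* variables (age,
   gender) that cannot oscillate within a day; the ratio of their r² to the
   outcome's r² measures whether the outcome's wave exceeds what selection
   alone produces.
4. **A seeded synthetic-data generator** with named scenarios (`null`,
   `circadian`, `selection_only`, `mixed`, `gender_phase_shift`,
   `age_phase_gradient`, `dst_phase_shift`) emulating the demographic,
   temporal, and timezone structure of a large US online study, so the whole
   pipeline is testable without any external data.

Server timestamps are converted to local clock time through an explicit zone
table (half-timezone counties coded as 0.5-hour offsets; DST rules supplied
as data, not taken from the OS), and records on DST transition days are
excluded.

## Worked example

```r
library(cosinorsel)

report <- run_pipeline(run_config(preset = "circadian", n = 200000, seed = 7))
print(report$objects$fit_adjusted)
```

```
24-h cosinor fit
  mesor -0.0031983  amplitude 0.01671  acrophase 20:37 (20.613 h)
  variance explained 0.07982%  F(2, 198958) = 79.47, p = 3.17e-35  (n = 198961)
```

The `circadian` preset injects a weak rhythm — 0.08% of residual variance,
peaking at 21.17 h (9:10 pm) — into 200,000 synthetic records. The adjusted
fit recovers it: the realized variance explained (0.0798%) matches the
target, the acrophase lands at 20:37 (about half an hour from the injected
peak — at this rhythm strength and sample size the phase estimate carries a
sampling error of tens of minutes, a caveat the methods vignette develops),
and the joint F test is decisive despite the rhythm explaining less than a
tenth of a percent of the variance, which is exactly why large online
datasets surface such effects. `report$part2` holds the DST/gender/age
moderation blocks and `report$part3` the fixed-variable benchmark ratios;
with `out_dir` set, the same content is written as JSON, per-model CSVs and
a log of exclusion counts.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/cosinorsel-cli.R", package="cosinorsel"))')" \
  run --preset selection_only --n 100000 --seed 1 --out results/sel
```

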