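# hcsa

Cardiac phenotyping of embryonic hearts from time-lapse videomicroscopy
by **hemoglobin contrast subtraction angiography (HCSA)**.

Hemoglobin absorbs green and blue light far more strongly than red, so
in an ordinary color acquisition of an optically accessible embryonic
heart (a tadpole or fish larva), blood darkens one channel and not the
other. Subtracting the strongly absorbed channel from the weakly
absorbed one yields an endogenous blood-contrast image — an angiogram
with no injected dye. `hcsa` quantifies ventricular function from such
series for screening studies in which cohorts of embryos (control vs
gene knockdown, control vs teratogen exposure) must be compared
objectively.

## What it computes

Given an image series and per-frame ventricle outlines, the pipeline
selects the end-diastolic (ED) and end-systolic (ES) frames from the
hemoglobin-blush trace, classifies hemoglobin-containing pixels inside
the ventricle with an internally implemented Otsu threshold
(256 equal-width bins, between-class variance
ω₀ω₁(μ₀−μ₁)² maximized over bin edges), and reports per embryo:

| metric | definition |
|---|---|
| `tEDA`, `tESA` | segmented ventricular area (px²) at ED / ES |
| `delta_pct_tA` | 100·(tEDA − tESA)/tEDA |
| `EDBA`, `ESBA` | hemoglobin (blood) area at ED / ES |
| `SA` | stroke area, EDBA − ESBA |
| `EF` | ejection fraction, 100·SA/EDBA |
| `MMI` | myocardial mass index, tESA − ESBA |

Groups are compared metric-by-metric with a two-sided unpaired
Mann–Whitney test (exact by full enumeration for small tie-free
samples, tie-corrected normal approximation otherwise) and medians
with distribution-free 95% confidence intervals from binomial order
statistics.

A synthetic beating-heart phantom (`simulate_heart_series()`,
`simulate_cohort()`) with analytically known ground truth backs the
entire test suite: a contracting elliptical blood pool inside a
myocardial annulus, imaged through the same two-channel absorption
model with seeded sensor noise.

## Worked example

```r
library(hcsa)

# phantom with a true ejection fraction of 50%
sim <- simulate_heart_series(phantom_params(seed = 1))
res <- quantify_series(sim$series, sim$rois, run_config())
res$metrics
#> VentricleMetrics:
#>   tEDA 14520.0  tESA 7984.0  d%tA 45.01%
#>   EDBA 11255.0  ESBA 5612.0  SA 5643.0  EF 50.14%  MMI 2372.0
#>   ED frame 20, ES frame 25
```

The recovered ejection fraction (50.14%) sits within a fraction of a
percentage point of the phantom's analytic truth (50%); the selected
frames land exactly on analytic extremes of the blood-area waveform
(frames 20 and 25 are an ED and an ES of the 10-frame cycle).

```r
# control vs impaired-emptying cohort (ES semi-axes x1.15, n = 30/30)
cohort <- simulate_cohort(phantom_params(),
                          effect = list(blood_semi_axes_es = 1.15),
                          n_per_group = 30, base_seed = 1)
cmp <- compare_cohorts(cohort$truth_table, c("control", "treated"))
cmp[cmp$metric == "EF", c("metric", "U", "p", "median_a", "median_b")]
#>   metric   U         p median_a median_b
#> 7     EF 895 4.975e-11    50.78    36.63
```

The treated group's median EF drops by ~14 points and the Mann–Whitney
p-value is far below 0.05 — the package resolves an impaired-emptying
phenotype of this size essentially every time at 30 embryos per arm.

## Command line

A thin dispatcher over the same functions is installed at
`system.file("cli", "hcsa", package = "hcsa")`:

```sh
hcsa simulate --out-dir phantom --seed 7
hcsa quantify --series phantom/stack.tif --roi phantom/roi.csv --out metrics.csv
hcsa compare  --tables control.csv,treated.csv --groups control,treated --out cmp.csv
```

Every output table is accompanied by a JSON run record (config
snapshot, input paths, software version, per-stage log).

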