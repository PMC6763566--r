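---
title: "Quantifying embryonic ventricular function from hemoglobin-contrast video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying embryonic ventricular function from hemoglobin-contrast video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsa)
```

## The measurement problem

Embryonic hearts of optically accessible model organisms (amphibian
tadpoles, fish larvae) can be imaged through the body wall with an
ordinary color camera. Hemoglobin absorbs green and blue light far more
strongly than red, so blood appears as a dark "blush" in a strongly
absorbed channel while the surrounding tissue does not. Subtracting the
strongly absorbed channel from a weakly absorbed one therefore yields an
endogenous angiographic contrast — no dye injection, no harm to the
animal, repeatable across developmental stages.

`hcsa` turns a time-lapse series of such frames plus a manually
segmented ventricle outline into eight per-embryo measures of
ventricular anatomy and pump function, and compares cohorts of embryos
(for example control versus gene-knockdown or teratogen-exposed groups)
with nonparametric statistics. Because every stage of the chain is a
potential source of bias, the package ships a synthetic beating-heart
phantom whose true metric values are known analytically; all claims the
test suite makes about accuracy are claims about recovery of that
ground truth.

## The processing model

For a series of frames $I_t$ the pipeline computes:

1. **Hemoglobin contrast.** In `channel_difference` mode,
   $C_t = I_t^{\mathrm{weak}} - I_t^{\mathrm{strong}}$, min–max
   normalized to $[0,1]$ using one global minimum and maximum over the
   *whole series*. The global normalization matters: it keeps contrast
   values on the end-diastolic and end-systolic frames on a common
   scale, so that differences in thresholded pixel counts between the
   two frames reflect blood area rather than per-frame renormalization.
   `single_channel_inverted` mode ($1 -$ normalized intensity) serves
   grayscale acquisitions where blood is simply dark.

2. **Phase selection.** A per-frame Hb-blush trace (pixels above a
   provisional Otsu threshold, inside the union of all supplied ROI
   outlines) is optionally smoothed by a centered moving average
   (`smoothing_window`, odd, default 1 = off, edges truncated). The
   trace maximum is end-diastole (ED, maximal filling), the minimum
   end-systole (ES, maximal ejection); ties break to the earliest
   frame. A constant trace raises a *no pulsatility* error rather than
   returning an arbitrary pair. Manual indices can be supplied instead
   (`phase_selection = "manual"`), which is the faithful equivalent of
   picking frames by eye.

3. **Thresholding.** Otsu's method is implemented in the package
   itself: contrast values are histogrammed into `otsu_bins`
   (default 256) equal-width bins over their observed range, and the
   interior bin edge maximizing the between-class variance
   $\omega_0\omega_1(\mu_0-\mu_1)^2$ (computed from bin counts and
   midpoints) is the threshold; the classification rule is
   *value > threshold ⇒ hemoglobin-containing*. Ties break toward the
   lowest qualifying edge, which is deterministic and blood-inclusive.
   By default the ED- and ES-frame ROI values are pooled into one
   histogram (`otsu_pooling = "pooled_over_selected_frames"`), so both
   frames share one threshold; the per-frame alternative exists because
   it is not known whether historical implementations pooled, but a
   shared threshold prevents threshold drift from masquerading as
   stroke area.

4. **Metrics.** With $tEDA, tESA$ the segmented ventricle pixel areas
   and $EDBA, ESBA$ the Hb-blush counts at ED and ES:
   $$\Delta_\%tA = 100\,(tEDA - tESA)/tEDA,\quad
     SA = EDBA - ESBA,\quad EF = 100\,SA/EDBA,\quad
     MMI = tESA - ESBA.$$
   The myocardial mass index rests on the assumption that at peak
   systole nearly all blood has left the ventricle, so segmented area
   minus residual blood area approximates myocardial tissue area.
   Negative stroke area (paradoxical filling) is reported and flagged,
   never clamped. All areas are pixel counts; `scale_metrics()` applies
   an optional µm/px calibration at output only.

5. **Group statistics.** Each metric is compared between groups by a
   two-sided, unpaired Mann–Whitney test. With both groups of size ≤ 8
   and no ties the p-value is exact, by full enumeration of all
   $\binom{n_a+n_b}{n_a}$ assignments
   ($p = 2\,P(U' \le \min(U, n_an_b - U))$, capped at 1); otherwise a
   normal approximation with tie-corrected variance and continuity
   correction is used. The cutover at 8 keeps enumeration at
   $\le \binom{16}{8} = 12870$ arrangements. Medians carry
   distribution-free 95% confidence intervals from binomial order
   statistics: the smallest symmetric rank pair $(l,\,n{+}1{-}l)$ whose
   coverage $P(l \le B \le n-l)$, $B \sim \mathrm{Bin}(n, 1/2)$,
   reaches 0.95. For $n < 6$ no such interval reaches 95% and the
   sample range is reported with a warning. No multiple-testing
   correction is applied — each metric is judged at $\alpha$
   per-comparison, and the output's `method` column records
   `uncorrected` so downstream users can apply their own.

## Conventions that had to be fixed

* **Coordinates and indices.** Pixel coordinates are 0-based, x
  rightward, y downward, with integer coordinates at pixel centers;
  frame indices are 0-based in every file format and result. These
  conventions are arbitrary but must be fixed exactly for rasterization
  to be testable.
* **Rasterization rule.** A pixel belongs to the ROI iff its center
  satisfies the even–odd rule; centers exactly on an edge are included.
  No partial-pixel weighting: downstream measurements are whole-pixel
  counts, so the mask is too. The suite checks this against an
  exhaustive per-pixel oracle (with an independently coded test and a
  differently oriented ray) and against shoelace areas for large convex
  polygons (< 2% relative error above 500 px²).
* **Image containers.** 8/16-bit PNG and single/multi-page TIFF are
  read without any intensity rescaling; 14-bit data ride in 16-bit
  containers untouched, which is safe because Otsu is invariant to
  affine intensity maps. Series are written as TIFF (bit-exact round
  trip); PNG output is restricted to 8-bit series because the
  available PNG writer emits 8-bit files only.
* **ROI sidecar.** A deliberately minimal text dialect
  (`#hcsa-roi v1`; one `frame,vertex,x,y` record per line) defined by
  this package, with vertex order preserved and polygons validated
  (≥ 3 vertices, in-bounds, simple).

## The phantom and what it does (not) model

`simulate_heart_series()` renders an elliptical blood pool whose
semi-axes follow a raised cosine between their ED and ES values
($t = 0$ at ED), surrounded by a myocardial annulus of fixed thickness,
in three channels (red uniform; green/blue attenuated by
$e^{-k}$ with $k$ = `hb_absorption` (default 0.7) in blood and
`myocardium_absorption` (default 0.15) in wall, on a signal level of
15000 counts in a 16-bit container), plus seeded additive Gaussian
noise (`noise_sd`, default 0.05 of signal). Ground truth —
per-frame blood area $\pi a(t) b(t)$, the sampled-frame extremes and
all eight metrics — is computed analytically and satisfies the metric
identities exactly by construction.

Default acquisition geometry is 50 frames at 0.2 s. The default
contraction rate is 0.5 Hz: 10 frames per cycle, so ED and ES phases
land exactly on sampled frames and 50 frames span 5 full cycles. The
generator refuses parameter sets sampling fewer than 4 frames per
cycle, for which the area extremes would be unresolvable; real
embryonic hearts beat faster, but the phantom's purpose is a resolvable,
analytically known waveform, not hemodynamic realism. ROI outlines
(64-gons of the outer ellipse) are provided at *every* frame attaining
the extreme blood area, since under noise the measured extreme can fall
in any cycle.

`simulate_cohort()` adds per-embryo biological variability: each of the
four semi-axes is jittered by an independent lognormal factor
(`sdlog = 0.05`), giving within-group EF standard deviations around
5 percentage points — enough overlap that group comparisons are
non-trivial. Effects are expressed as named parameter multipliers
applied to the second group before jitter (e.g.
`list(blood_semi_axes_es = 1.15)` for impaired emptying); the
multiplied parameters are validated per embryo, and a post-jitter ES
axis that would exceed its ED axis is capped at it (that axis fails to
contract) so the generator never emits an invalid heart. All
randomness derives from one base seed; per-embryo image seeds are drawn
deterministically from it.

The phantom deliberately omits optical scattering and point-spread
blur, trabeculation, red-blood-cell granularity, pericardial
structures, motion between channel exposures, and segmentation error
(its ROIs are exact 64-gon outlines). Passing recovery tests therefore
demonstrates correctness of the measurement chain — contrast
arithmetic, thresholding, counting, phase picking, formulas — not
robustness to the full messiness of microscope data; in particular,
manual segmentation variability enters real measurements and has no
counterpart here.

## Numerical choices

* Otsu candidates are the 255 interior edges of a 256-bin histogram
  over the observed range — classic 8-bit behavior, applicable to
  continuous values; criterion computed via cumulative moments,
  verified in tests against a naive per-edge evaluation.
* Exact Mann–Whitney uses midrank sums over enumerated assignments
  (valid with ties, though the auto policy only takes the exact branch
  tie-free); comparisons of half-integer statistics carry a 1e-9
  absolute guard against floating error.
* Degenerate inputs fail loudly and specifically: constant series
  (no contrast), constant blush traces (no pulsatility), all-equal
  threshold inputs, empty samples, polygons with < 3 vertices or
  self-intersections, blush counts exceeding ROI areas.
* `EDBA = 0` makes EF undefined and is an error, not an `NaN`.

## Problem sizes used in validation

The shipped suite validates on 128×128 phantoms of 20 frames for most
end-to-end checks and full 256×256, 50-frame phantoms for the
contractility sweep (true EF 30/50/70%); cohort statistics run on
analytic ground-truth tables (30 + 30 embryos for power, 500 replicate
null cohorts of 15 + 15 for size). These sizes were chosen as the
smallest at which the geometry is comfortably resolved (blood-pool
radii ≥ 20 px keep pixelation error under ~2%) and the statistical
checks have narrow enough Monte-Carlo error to be meaningful.

## A worked example

```{r example, eval = FALSE}
library(hcsa)

# a phantom with 50% true ejection fraction
sim <- simulate_heart_series(phantom_params(seed = 1))
res <- quantify_series(sim$series, sim$rois, run_config())
res$metrics          # recovered EF is within a fraction of a point
sim$truth$EF_true    # 50

# a control vs impaired-emptying experiment on ground-truth tables
cohort <- simulate_cohort(phantom_params(),
                          effect = list(blood_semi_axes_es = 1.15),
                          n_per_group = 30, base_seed = 1)
compare_cohorts(cohort$truth_table, c("control", "treated"))
```

## Known limitations

* One ED/ES pair per series (the global extremes); beat-by-beat
  variability is out of scope.
* Single simple polygon per frame: no holes, no multi-chamber ROIs.
* Areas are 2-D projections; no volumetric extrapolation is attempted,
  so EF here is an area-based analogue of the clinical quantity.
* The auto phase picker uses the blush trace; when per-frame ROIs
  differ strongly, a silhouette-based trace could disagree.
* The median confidence interval is the order-statistic construction;
  plotting software may draw different 95% bars for the same data.
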