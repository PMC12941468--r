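---
title: "Methods: image-based shell carbonate carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based shell carbonate carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellcarbon)
```

## The estimation problem

Settlement panels immersed in coastal waters accumulate calcifying fouling
organisms, chiefly barnacles and bivalves, whose shells are a standing
stock of carbonate carbon. The conventional census is destructive: the
panel is scraped, organisms are dried, weighed and assayed. `shellcarbon`
implements the non-destructive route: a photograph of the panel plus
pixel-level instance masks of the organisms yields, per individual, the
projected shell dimensions, an allometric estimate of the dry shell
weight, and the carbonate carbon it implies.

The chain for one individual is

1. mask → projected length $L$ and width $B$;
2. $A = \frac{\pi}{4} L B$, the equivalent projected ("attachment") area —
   the area of the ellipse with $L$ and $B$ as axes;
3. $W = v\,\alpha\,A^{\beta}$, a species-specific power law with valve
   factor $v$;
4. $C = W \times C_{\mathrm{carbonate}}$, with the species' measured
   carbonate-carbon mass fraction.

Totals per panel are sums over individuals; across-panel comparisons
(month, surface material) are unweighted means over the panels in each
group.

All model assumptions sit in steps 2–4: the top-view outline is close to
an ellipse; shell mass scales as a power of its projected footprint within
a species; and the carbon fraction of dried shell material is constant per
species. These hold to the few-percent level for the sessile calcifiers
the package targets but degrade for strongly non-convex or heavily
overgrown individuals.

## Parameters and defaults

| quantity | barnacle | bivalve | units | role |
|---|---|---|---|---|
| $\alpha$ | 0.1597331 | 0.0622163 | g·cm$^{-2\beta}$ | allometric scale |
| $\beta$ | 1.60845 | 2.54634 | — | allometric exponent |
| valve factor $v$ | 1 | 2 | — | outline-to-animal multiplier |
| $C_{\mathrm{carbonate}}$ | 0.1207 | 0.1214 | — | carbon mass fraction |

The barnacle $(\alpha, \beta)$ come from a direct nonlinear fit of
caliper/balance calibration data; the bivalve values are literature
parameters for a morphologically similar species, adopted because local
bivalve calibration samples were scarce, and validated by transfer
(`validate_transfer()` reports the fixed-parameter $R^2$). Carbon
fractions are isotope-ratio mass-spectrometry measurements on pooled dried
shells. Every value is overridable through `builtin_params(overrides = )`.

**The valve factor deserves emphasis.** With the bivalve $(\alpha, \beta)$
above, the bare power law $\alpha A^\beta$ under-predicts reference
bivalve dry weights by a factor of almost exactly two, while $2\alpha
A^\beta$ reproduces them to print precision (the test suite brute-forces
$v \in \{1, 2\}$ against all reference bivalve rows). The natural reading
is that the literature parameters describe a single valve while the
projected outline stands for the whole two-valved animal. Because this
convention is inferred from arithmetic rather than stated theory, `v` is
an explicit, documented, overridable field of the registry — if your
bivalve parameters already describe whole-animal mass, set `valve_factor
= 1`.

## Dimension estimation from masks

`extract_dimensions()` supports two estimators.

The default, `method = "ellipse"`, takes the axes of the mask's
moment-equivalent ellipse: the eigenvalues $\lambda_1 \ge \lambda_2$ of
the second-central-moment matrix of the foreground pixel centers (plus
$1/12$ per axis, the variance of a unit pixel square) give $L = 4
\sqrt{\lambda_1}$, $B = 4\sqrt{\lambda_2}$ in pixels. This is the
major/minor-axis convention of standard region-properties tooling. Because
it averages over every foreground pixel, its error on convex shells is
well under 1% at 40 px/cm and ~2% at 20 px/cm for the benchmark
population.

`method = "rect"` reports the side lengths of the minimum-area rotated
rectangle of the pixel-center convex hull (rotating calipers), plus one
pixel per side so the value refers to pixel footprints rather than center
spans. It is the more literal reading of "projected length/width", and for
an axis-aligned rectangular mask it returns the exact side lengths. It is
**not** the default for two measured reasons. First, for near-circular
outlines (barnacle aspect ratios 0.85–1) the minimizing orientation is
decided by rasterization noise, and a bounding square tilted ~45°
frequently wins, biasing $L$ low and $B$ high by up to ~10% even on
50-pixel shells. Second, for any outline the rectangle depends only on the
few extreme boundary pixels, so its quantization error is a half pixel per
side — several percent on small shells — where the moment estimator's
error shrinks with the pixel count.

There is also a hard information limit worth knowing: probing the set of
ellipses whose rasterization reproduces a given mask exactly shows that
below roughly 16 px per axis the consistent parameter band itself is wider
than 3%, so *no* estimator can certify a few-percent dimension from a
binary mask at such sizes. At the package's reference bench resolution of
40 px/cm this corresponds to a 4 mm axis; panel photography at realistic
camera resolutions (≥ 120 px/cm for a 25 cm panel on a modern sensor)
pushes the limit well below every annotatable organism.

Dimensions are reported in millimetres (the reporting convention of the
reference tables); the area formula converts to centimetres internally.

## Allometric fitting

`fit_allometric()` fits $W = v\,\alpha A^{\beta}$ with $\alpha, \beta > 0$
by Levenberg–Marquardt, initialized from the ordinary least-squares line
of $\log W$ on $\log A$ and capped at 200 iterations with a relative
SSE tolerance of $10^{-10}$.

Calibration error from balances and calipers is multiplicative — a 15%
coefficient of variation, not a fixed gram error — so the default
objective minimizes *relative* residuals, $\sum_i ((W_i - f_i)/f_i)^2$,
by iteratively reweighted least squares (weights $1/f_i^2$ refreshed from
the current fit, three passes). Under multiplicative noise the unweighted
raw-scale objective concentrates its leverage as $A^{2\beta}$ — with
$\beta \approx 1.6$ effectively the few heaviest shells — and simulation
at a 15% CV and $n = 200$ shows its $\beta$ estimate scatters with SD
$\approx 0.11$, versus $\approx 0.015$ for the relative objective. The
unweighted objective remains available as `weighting = "absolute"`.

$R^2$ is always reported on the untransformed weight scale, $1 -
\mathrm{SSE}/\mathrm{SST}$, with the log–log $R^2$ kept as a diagnostic
(`glance()` shows both). Degenerate inputs — fewer than 3 samples,
non-positive values, all areas identical — raise typed errors rather than
returning coefficients.

## The synthetic scene generator

`scenario_spec()` + `simulate_scene()` render panels whose ground truth is
known analytically, so segmentation, geometry and carbon accounting can be
tested end-to-end without a trained network or real imagery.

Shell footprints are ellipses: convex, parametric, and carrying exact
true $L$ and $B$. Barnacles are near-circular (aspect 0.85–1.00) with a
radial ridge intensity texture; bivalves elongated (aspect 0.50–0.72)
with an axial shading gradient. Placement is dart-throwing: a candidate
is rejected when its mask overlap with any accepted shell exceeds
`max_overlap` (default 0) as a fraction of the smaller mask. Scenes add a
linear illumination ramp, a smooth sinusoidal background texture and
Gaussian pixel noise, each with its own amplitude (set all three to zero
for an analytically flat background). One seed drives placement and
rendering; identical seeds give byte-identical scenes.

Sizes follow a truncated lognormal per class: barnacle median 12 mm
(geometric SD 1.3, floor 6 mm), bivalve median 22 mm (geometric SD 1.4,
floor 8 mm) — a settled community of adult calcifiers. The floors encode
the annotatable-size detection limit discussed above: sub-floor recruits
exist on real panels but cannot be dimensioned reliably at bench
resolution by any estimator, and medium-to-large individuals dominate the
carbon stock in any case (in the packaged reference panel the single
largest bivalve carries 97% of the total carbon). The default bench
resolution is 40 px/cm on a 25 × 35 cm panel.

What the generator does *not* emulate: algae and biofilm cover, partial
occlusion and three-dimensional stacking, non-elliptical or damaged
outlines, specular lighting, and annotation error. Passing the synthetic
suites therefore demonstrates the correctness of the measurement chain on
clean convex instances — not field performance of any particular
segmenter, which must be established against real annotated imagery.

## Segmentation: tiling, baseline, stitching

High-resolution panels are processed in 512-pixel sliding windows
(stride = window − overlap, default overlap 64 px; the last tile per axis
is anchored to the image edge so coverage is complete). Per-tile
detections are translated into panel coordinates and fused: two instances
merge when their mask IoU exceeds 0.5 *or* the smaller is ≥ 80% contained
in the larger — the containment clause catches the fragment-vs-whole case
where IoU is structurally low — and merging is transitive over the
resulting graph. The merged mask is the pixel union; the score is the
maximum; the class follows the highest-scoring member, after which the
baseline pipeline re-derives classes from the merged masks (a shell cut by
a tile boundary would otherwise keep the class its fragment suggested).

The bundled baseline segmenter is deliberately classical: least-squares
removal of a linear illumination plane, Otsu thresholding, a 5-px disc
opening, and marker-based watershed on the distance transform to split
touching blobs; components under `min_area_px` (default 10 px) are
dropped so speckle never enters carbon totals. Classes come from an
elongation rule (moment-ellipse aspect below 0.78 → bivalve) and scores
from component solidity. On noiseless rendered scenes it recovers every
instance; under the generator's default noise and illumination it holds
~0.95 recall but mediocre precision — it is a reference implementation and
test harness, not a competitor to a learned segmenter, and external
predictions enter through `ingest_external_predictions()` /
`read_coco()`.

Border-touching instances are retained (their clipped dimensions bias
low); filter them upstream if that bias matters for your panels.

## Evaluation metrics

Pixel IoU $= TP/(TP+FP+FN)$ and Dice $= 2TP/(2TP+FP+FN)$ are computed on
the class-agnostic union of instance masks, dataset-pooled. Instance
matching is COCO-style greedy: predictions by descending score, each
taking the highest-IoU unmatched same-class truth at or above the
threshold (default 0.5), one-to-one. AP uses the COCO interpolation —
monotone precision envelope sampled at 101 recall levels — averaged over
IoU 0.50:0.05:0.95 per class, then over classes present in the ground
truth; small-object recall restricts the denominator to truths below
$32^2$ px. Dimension agreement is the squared Pearson correlation of
pooled model-vs-manual measurement pairs; note a constant multiplicative
bias still yields 1 — it measures association, not identity.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, origin top-left; boxes are half-open
  `(x, y, w, h)` (COCO convention). Masks are stored bbox-cropped.
* Polygon rasterization is even-odd scanline sampled at pixel centers
  $(x+0.5,\,y+0.5)$; COCO output uses uncompressed column-major RLE, which
  round-trips pixel-exactly.
* The pixel scale of a panel is the mean of the two axis ratios; a >2%
  axis disagreement triggers a warning (the image frame is assumed to
  coincide with the panel — no corner detection or homography is
  attempted).
* Degenerate masks (under 3 pixels, collinear pixels) raise typed
  geometry errors; `dimension_table()` logs and skips them rather than
  zeroing.
* Undefined metrics (both masks empty; no small truths) raise typed
  errors at the operation level; the bundled `evaluate_predictions()`
  reports such cells as `NA`.
* Ties in merging resolve toward the higher detection score; ties in
  matching toward the higher IoU.

## Problem sizes used by the test suite

The shipped suites run a 16-shell scene at 20 px/cm for segmentation and
metric tests, a 60-shell 1000 × 1400 px scene at 40 px/cm for the
end-to-end pipeline check, 20 replicate calibration fits at $n = 200$ for
recovery coverage, and 1,000 random mask pairs for the Dice–IoU identity.
These sizes exercise every code path at full fidelity; nothing in the
method is approximated at them.

## Known limitations

* Dry weight is inferred from a 2-D footprint; shell height variation
  within a species is absorbed into $\alpha$ and $\beta$ and not modelled.
* No uncertainty propagation: carbon totals are point estimates.
* The bivalve parameters are a literature transfer validated at panel
  scale, not a local calibration.
* Sub-floor recruits (axes under ~16 px at the working resolution) cannot
  be dimensioned to the few-percent level from binary masks — at bench
  resolutions, count them, don't measure them.
* The baseline segmenter assumes bright convex organisms on a darker,
  smoothly varying background.
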