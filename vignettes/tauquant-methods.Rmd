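---
title: "Quantifying tau pathology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tau pathology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauquant)
```

## The measurement problem

Staging Alzheimer-type tau pathology across a cohort requires comparing
the burden of phospho-tau immunoreactivity between brains, regions and
disease stages. Manual scoring is rater-dependent; the approach
implemented here is a fixed, macro-style measurement that is run with
identical parameters on every image, so results are reproducible and
free of per-image judgement calls. The measured quantity is the
**immunoreactive (IR) area in percent**: the fraction of the imaged
field covered by detected marker-positive objects.

The main confounder in aged human brain tissue is autofluorescence,
dominated by lipofuscin granules, which are bright in *every* emission
channel. The pipeline therefore images an unlabeled autofluorescence
channel alongside the marker channel and removes everything that is
bright in it.

## The pipeline, stage by stage

`quantify_marker()` composes the stages in a fixed order; each is also
exported on its own.

1. **Z-projection** (`project_stack`): fields captured at several
   z-levels are reduced by per-pixel maximum.
2. **Background correction** (`correct_background`): the smooth
   background (uneven illumination, diffuse light) is estimated as a
   large-scale Gaussian lowpass of the image and subtracted, clipping at
   zero. The scale (`background_sigma_um`, default 50 µm) must stay well
   above the largest object diameter, or objects are flattened into
   their own background estimate. The lowpass is computed exactly as a
   separable pair of dense kernel-matrix products with truncated,
   renormalized kernels at the borders; renormalization keeps a constant
   image constant, which makes "flat field maps to zero" an identity of
   the operator rather than an approximation.
3. **Autofluorescence masking** (`autofluorescence_mask` +
   `subtract_mask`): the AF channel is thresholded (default: fixed
   15000 on the 16-bit scale) and the mask dilated one pixel to swallow
   the sub-threshold rim that thresholded granules keep; masked pixels
   in the marker channel are set to zero. Masked pixels remain in the
   ROI denominator: the reported percentage is of the full imaged field.
4. **Edge enhancement** (`edge_enhance`): a high-boost filter,
   `img + k · (img − lowpass(img, 1 µm))`. Its purpose is to steepen
   object rims so that the subsequent global threshold cuts closer to
   the true boundary; strength 0 is the identity, and a constant image
   is unchanged at any strength.
5. **Detection** (`detect_objects`): global threshold, 8-connected
   components, then size and shape restrictions in physical units
   (area in µm² via `pixel_size²`; roundness `4πA/P²`, clamped at 1
   because discretized perimeters overshoot slightly for compact
   objects). Mean object intensity is measured on the *raw* image --
   outlines are carried back to the unprocessed data.
6. **Reduction** (`measure_ir_area`): percent IR area over the full
   field, with the object count.

### Thresholds

Per-image Otsu keeps the procedure rater-independent, but Otsu's
between-class criterion is known to fail on images that genuinely
contain no signal class: the optimum then lands inside the noise and
fabricates objects. A batch pipeline must process marker-negative
control sections with the same settings as heavily diseased ones, so
the default signal threshold is Otsu with a floor
(`threshold_spec("otsu", floor = 8000)`): the threshold never drops
below a calibrated minimum that sits far above the post-correction
noise yet far below true object intensities. Every threshold can
instead be fixed per marker in the run configuration.

### Plaque cores versus tangles

On the ThioflavinS channel, plaque cores are intensely labeled while
tangles are only weakly ThioS-positive. `detect_plaque_cores` exploits
both properties: a fixed threshold (default 15000) that weak tangle
labeling does not reach, plus a minimum-area restriction (default
200 µm²) that removes small bright objects such as lipofuscin. No edge
enhancement is applied at this stage. The discrimination is thus doubly
protected: a tangle would have to be both unusually bright and unusually
large to intrude.

## The synthetic-section generator

Real staged cohorts cannot be shipped, so every stage of the pipeline is
validated against `generate_section()`, which renders 16-bit
multi-channel fields with exact per-class ground truth:

* **tangles** — anisotropic Gaussians thresholded at half maximum
  (rotated ellipses, axis ratio 2–3), 15–30 µm across, in the signal
  channel and at 30 % brightness in the ThioS channel;
* **threads** — random-walk polylines dilated to 1–2 µm width;
* **plaque cores** — discs 30–80 µm across with a bright core and a
  radial falloff to 60 % at the rim, in the ThioS channel;
* **lipofuscin** — 1–5 µm granules rendered at full AF intensity in
  *every* channel (their defining property);
* **nuclei** — 6–10 µm discs in the counterstain channel.

Overlaps are resolved by the fixed priority order plaque > tangle >
lipofuscin > thread > nucleus, so the ground-truth masks are disjoint
and the per-class area fractions are exact pixel counts. Object classes
with a numeric burden target are placed by an accept-if-closer rule:
a candidate is kept only if it moves the realized fraction toward the
target, which tracks targets to within about half an object's area. The
smallest reachable burden is therefore one minimal object per field;
targets below that resolve to the nearest achievable value, which the
ground truth reports exactly.

Illumination is a shared low-order 2-D polynomial gradient (default
±30 % of background). Shot noise is applied as the variance-matched
Gaussian approximation of a Poisson process (exact at the photon counts
simulated, ≥ 100 per pixel), plus additive Gaussian read noise.
Intensity defaults (signal 30000, AF 30000, background 2000 on the
16-bit scale) give contrasts typical of well-exposed fluorescence
micrographs.

What the simulator deliberately does **not** model: optics (no PSF),
3-D tissue context, mosaic stitching artifacts, staining chemistry,
spectral bleed-through. Passing the recovery suite therefore shows the
measurement procedure is correct *given* its imaging model, not that
any particular threshold matches a particular microscope; on real data
the per-marker thresholds must be calibrated once and then frozen.

## Study structure and aggregation

A simulated study mirrors a staged cohort: 4 Braak-stage groups
(control, I/II, III/IV, V/VI) × 5 cases × 5 regions (temporal, frontal,
cingulate, occipital cortex and the transentorhinal region), with two
mosaic fields per (case, region). The two mosaics are simulated as
independent fields and their measurements combined by the arithmetic
mean (`average_mosaics`) — the least surprising reduction, isolated in
one function so a pooled-area alternative could replace it. Per-case
biological variability is a lognormal multiplier (σ = 0.25) on the
pathology burdens.

The default burden design rises monotonically with stage and is higher
in the transentorhinal region, where tau pathology begins, than in the
isocortex (isocortical tangle burden 0.4 %→0.6 %→1.2 %→3.5 %; TEntR
0.4 %→1.0 %→2.2 %→5.0 %; threads at half the tangle burden). The floor
of 0.4 % is the smallest burden resolvable at the 128 × 128 µm study
field (one small tangle); larger fields would allow lower floors at
proportional cost.

Aggregation follows the conventions of staged-cohort reporting:
`isocortex_mean` adds a synthetic "Isocortex" region as the per-case
mean of the four isocortical regions (never the transentorhinal
region); `fold_change` reports group means relative to the control
group per (region, marker), anchored at exactly 1 for controls and
flagging (not infinitizing) a zero control mean; `apply_exclusions`
removes case/marker-scoped rows under explicit, logged rules, since
outlier exclusions must be user-specified, never automatic.

## Statistics

* `two_way_anova` — Braak group × region with cases as replicates.
  Balanced designs use the classical decomposition (verified against a
  brute-force sums-of-squares oracle to 1e-8); unbalanced designs
  (exclusions break balance) switch to type-II sums of squares, the
  standard choice when interactions are of secondary interest. When the
  omnibus ANOVA finds any significant term, Bonferroni-adjusted
  cell-mean contrasts are computed in two families: stage groups within
  each
  region and regions within each stage group, each family using its
  own multiplier m (logged in the output).
* `one_way_anova` — omnibus F plus both studentized-range post-hoc
  procedures: Tukey's HSD (Tukey–Kramer for unequal n) and the
  Newman–Keuls stepwise procedure, in which the critical value depends
  on the span of each comparison and a non-significant span seals all
  nested comparisons. At the full span the two coincide, so
  Newman–Keuls is never more conservative than Tukey there — a property
  the test suite checks on random data. Which post-hoc applies to which
  analysis is an explicit argument; the package refuses to guess.
  With zero residual variance the F statistic is reported as `NA`
  (degenerate flag) rather than an astronomic number.
* `ks_normality` — one-sample Kolmogorov–Smirnov distance to a normal
  with the sample's mean and SD. Because the parameters are estimated
  from the data, the honest p-value is Lilliefors' (default, n ≥ 5);
  the classical asymptotic null is available as a documented,
  anti-conservative alternative.
* `summarize_cases` — per-group demographic means reported at printed
  precision (1 decimal, rounding half away from zero), matching the
  convention of cohort tables. SEM is SD/√n with n counted after
  exclusions.

## Problem sizes and numerical choices

The test and acceptance suites run, by choice, at these scales:
recovery across burdens 0.1–10 % on 60 sections of 512² px (0.5 µm/px);
autofluorescence soundness and plaque discrimination on 20 seeded
sections each; the ANOVA oracle on 200 random balanced tables; the
end-to-end staged study (5 cases/group, 2 mosaics, 256² px fields) over
20 master seeds. Determinism is exact: a fixed (parameters, seed) pair
reproduces sections, measurements and CSV outputs byte for byte, and
generators restore the caller's RNG state. Seeds for study sections
derive from the master seed by a fixed affine counter scheme.

Known limitations worth restating: the defaults are calibrated on the
simulator's imaging model; the ROI denominator is the full imaged field
(grey- plus white-matter ROIs would need an explicit tissue mask); and
fold changes from near-zero control burdens are intrinsically unstable —
the generator's control floor keeps them finite, real cohorts may not.
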