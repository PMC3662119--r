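---
title: "Automated area-based percent mammographic density: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated area-based percent mammographic density: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodensity)
```

## The measurement

Mammographic breast density — the proportion of the projected breast area
occupied by radiodense fibroglandular tissue — is a major breast-cancer risk
factor, and area-based percent density on a continuous 0–100% scale is the
quantity with the best-established risk association. `mammodensity`
implements a fully automated area-based measurement for "For Presentation"
full-field digital mammograms (FFDM), single mediolateral-oblique (MLO)
views, together with the complete statistical toolkit needed to evaluate any
such algorithm against a panel of radiologists.

The measurement itself is the classic two-threshold construction:

1. **Breast envelope (ROI).** Using the View Position `(0018,5101)` and
   Image Laterality `(0020,0062)` DICOM header elements, the image is
   oriented chest-wall-left and a mask is built that removes the dark
   background, the pectoral muscle, a thin subcutaneous-fat (skin-line)
   margin, and any bright overlay text. What remains — the breast envelope —
   is the denominator.
2. **Dense-tissue threshold.** A gray-level histogram is built from envelope
   pixels only. Two classic thresholding methods are computed: Kapur's
   maximum-entropy threshold (maximise the sum of Shannon entropies of the
   two class-normalised histograms) and Tsai's moment-preserving threshold
   (choose the binarisation preserving the first three gray-level moments).
   The final threshold combines the two.
3. **Percent density.** `PD = 100 · |{envelope pixels > t}| / |envelope|`,
   reported together with its four-level BI-RADS density category
   (0–24%, 25–49%, 50–74%, 75–100%).

## Design choices in the density core

**Combination rule.** The published description of the algorithm this
package re-implements says only that "a variation" of the two thresholding
methods is applied. The package's documented rule is the arithmetic mean of
the two thresholds, with halves rounding down toward the lower gray level
(consistent with the lower-threshold tie-break inside the maximum-entropy
search). `min`, `max` and single-method alternatives are selectable via
`combine_thresholds(rule =)`, and the rule actually used is recorded in every
result's provenance, so the combination is fully auditable.

**Strict comparison.** Dense tissue is `value > t` (strictly above). The
alternative `>=` changes the count by exactly the number of pixels sitting
in the threshold bin; a test asserts this bound.

**Histogram policy.** One bin per native gray level up to 4096 levels
(12-bit); deeper scales are reduced to 4096 uniform bins. Thresholding
operates on the native "For Presentation" intensity scale; no vendor LUT is
inverted (the original study's vendor processing details are unknowable, so
this is a stated decision, not a fact about the published system).
`MONOCHROME1` images are inverted exactly once, at ingestion, so all
downstream code can assume bright = dense.

**Bimodality guard.** Both thresholding methods presuppose two gray-level
populations. Applied to an effectively unimodal envelope (an entirely fatty
breast) they split the single mode and would report roughly half the ROI as
dense. `compute_density()` therefore computes a scale-free class-separation
index at the final threshold, `d = (mu_high − mu_low)/sd_within`: splitting
a single Gaussian at its median yields `d ≈ 2.65` regardless of the noise
level, while genuinely separated tissue classes at plausible contrast give
`d ≥ 4`. Below `d = 3.2` the image is declared to have **no dense class**
(0% density, flagged in provenance). The symmetric failure mode — a 100%
dense breast, equally unimodal — is knowingly mapped to 0% as well: the two
cases are indistinguishable from intra-envelope contrast alone, and an
all-fat breast is the clinically realistic unimodal case.

**BI-RADS boundaries.** The density lexicon prints integer bins
("0–24%, 25–49%, …") for a continuous measure. The package reads them as
half-open intervals `[0,25) [25,50) [50,75) [75,100]`: 24.9% is category 1,
25.0% is category 2, and 75% or more is category 4 (extremely dense). This
boundary convention is a documented choice, not a claim about the source
lexicon's intent.

## Segmentation: what is removed, and how

The published pipeline names the structures removed but not the methods;
each stage here is a package design choice, swappable through
`segmentation_config()`:

* **Background** — Otsu threshold on the full histogram; background is
  restricted to below-threshold components touching a non-chest-wall border,
  so dark recesses inside the breast are not misread as background. The
  breast candidate is the largest remaining connected component.
* **Pectoral muscle** — `corner_region_growing`: a seed block in the
  chest-wall top corner is accepted only if its mean intensity stands
  clearly above the candidate median (otherwise "pectoral not found", an
  empty mask and a provenance flag, never an error); the region is then the
  connected component of candidate pixels within a noise-adaptive tolerance
  (four seed standard deviations) of the seed mean, confined to the
  chest-wall half of the image.
* **Overlay text** — bright connected components lying fully inside the
  background region with at least `min_text_component_area` pixels.
* **Subcutaneous fat** — 8-connected binary erosion of the skin line by
  `fat_peel_margin` pixels (default 3). Pixels beyond the image border count
  as tissue, so the chest-wall edge is never eroded. The margin default is a
  configuration value; the source study gives no quantitative definition of
  this step.

All segmentation runs in a normalised chest-wall-left orientation and the
masks are flipped back afterwards, which makes the whole stage
laterality-equivariant *by construction* (a property the tests verify
exactly). The four masks — envelope, pectoral, text, background — are
pairwise disjoint and tile the image.

Craniocaudal views, implants, and nipple/skin-line landmark detection are
out of scope; non-MLO inputs raise an unsupported-view error.

## The phantom: the world the tests live in

No clinical images ship with the package. Every downstream stage is instead
exercised on synthetic MLO phantoms with exact ground truth
(`generate_phantom()`), built from a four-intensity-class model — the
simplest world in which envelope masking and two-population thresholding are
meaningfully exercised:

* a half-elliptic breast envelope attached to the chest-wall edge
  (left for laterality L, right for R) on a dark background;
* a bright pectoral wedge anchored at the chest-wall top corner, running off
  the image top edge as in a real MLO projection;
* elliptic dense blobs painted inside the envelope until the dense pixel
  count equals `round(true_density · envelope_area)` — the last blob is
  truncated to its innermost pixels, so the achieved density equals the
  target to within one pixel (< 0.005), and the truth object stores the
  exact achieved ratio;
* optional bright glyph-like text blocks in background corners;
* additive Gaussian noise, clipped to the gray range.

Default intensities are background 10, fat 100, dense 180, pectoral 220 on
an 8-bit scale, with noise sd 4 — i.e. 5% of the fat–dense gap, a
well-separated but non-trivial contrast. The true-density distribution of
the original clinical sample is unknown, so batteries draw truths uniformly
on [0, 1]. Rating panels (`simulate_rater_panel()`) emit per-rater values
`clip(100·truth + bias_r + N(0, sd), 0, 100)` snapped to the 21-point
0,5,…,100 grid (ties round half away from zero), matching the visual
assessment protocol of a five-reader panel with 5% increments.

**What a green phantom test does and does not establish.** It establishes
that the masking geometry, the two thresholding methods, the combination
rule and the area ratio are implemented correctly, and that the pipeline
recovers known truth under the stated noise model. It does *not* establish
clinical performance: real parenchyma is textured, contrast varies by vendor
post-processing, pectoral boundaries are soft, and skin-line geometry is
irregular. The phantom deliberately omits scanner physics, compression
artifacts and photorealistic texture.

## Agreement evaluation

`evaluate_agreement()` composes the full statistical methodology for
validating a density algorithm against a reading panel:

* **Reference standard** — the per-subject median of the panel's visual
  assessments (mean of the central pair for even panel sizes, a documented
  convention a five-reader panel never hits).
* **ICC(2,1)** — two-way random-effects, absolute-agreement,
  single-measurement intraclass correlation, computed from the ANOVA mean
  squares, with a 95% CI by the McGraw–Wong F method. The absolute-agreement
  form is the one asymptotically equivalent to a quadratically weighted
  kappa, which is why it was chosen over consistency forms (available via
  `type = "consistency"`). The conventional interpretation scale (poor /
  fair / moderate / substantial / excellent at 0.20/0.40/0.60/0.80) is
  exposed as `icc_interpretation()`.
* **Quadratically weighted kappa** — over the 21-point grid, with
  `w_ij = (i−j)²/(K−1)²`; a simulation test holds the kappa–ICC equivalence
  to within 0.02.
* **Pearson correlation** — included deliberately as the *contrast*: a
  perfect linear relation (`y = 2x + 5`) has ρ = 1 with poor absolute
  agreement (ICC well below 0.9), the classic overstatement this evaluation
  methodology is designed to avoid.
* **Bland–Altman** — differences are `reference − algorithm` (positive bias
  means the panel reads denser than the algorithm); limits of agreement are
  `bias ± 1.96·sd` with the sample (n−1) standard deviation.
* **Within-one-category agreement** and per-category five-number summaries
  of reference densities (type-7 quartiles, Tukey 1.5·IQR whiskers — the
  source figure states no convention, so one is fixed and documented).

**The "promising" decision rule.** An algorithm is flagged promising when
its ICC against the reference standard falls within (or above) the 95% CI of
the radiologists' inter-rater ICC — implemented as
`ICC_alg ≥ CI_lower(panel ICC)`. The one-sided reading is deliberate: a
strict two-sided containment would disqualify an algorithm that agrees with
the reference *better* than the radiologists agree among themselves
(ICC = 1 for a perfect algorithm lies above any non-degenerate CI), which
cannot be the intent of the rule.

Degenerate inputs are handled explicitly rather than silently: a constant
ratings matrix has no defined ICC (error); a duplicate-rater matrix gives
ICC exactly 1 with a degenerate CI; zero residual variance with systematic
rater offsets yields the point estimate with a collapsed CI, since the
F-based interval is undefined there.

## Numerical conventions, in one place

| Quantity | Convention |
|---|---|
| Threshold semantics | low class = `value ≤ t`, dense = `value > t` |
| Maximum-entropy ties | lowest threshold |
| Combined threshold | mean of the two, halves rounded down |
| Moments fallback | non-real roots or `p0 ∉ (0,1)` → maximum-entropy threshold, flagged |
| Moments cumulative comparison | `cumfrac ≥ p0 − 1e-9` (absorbs float error in the closed form) |
| Bimodality guard | no dense class when separation index < 3.2 |
| BI-RADS bins | `[0,25) [25,50) [50,75) [75,100]` |
| Rating grid snap | nearest multiple of 5, half away from zero |
| Median (even raters) | mean of central pair |
| Bland–Altman sd | sample, n−1 |
| Quartiles / whiskers | type 7 / Tukey 1.5·IQR |
| Erosion | 8-connected, image border counts as tissue |

## Known limitations

* Single-view MLO only; craniocaudal geometry is different and unsupported.
* The pectoral model is a corner region grower tuned to wedge-like bright
  muscle; atypical pectoral shapes (concave boundaries, minimal corner
  presence) degrade to "pectoral not found" rather than a partial fit.
* A 100%-dense (unimodal-bright) breast is reported as 0% by the bimodality
  guard; see above.
* The DICOM layer reads uncompressed explicit/implicit VR little-endian
  single-frame grayscale only — the subset "For Presentation" FFDM exports
  use — and is not a general DICOM implementation.
* All performance statements shipped with the package are the ones its own
  tests compute on phantoms; no clinical accuracy is claimed.
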