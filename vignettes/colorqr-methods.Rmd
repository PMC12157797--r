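---
title: "Methods: Color QR colorimetry for free-chlorine readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Color QR colorimetry for free-chlorine readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorqr)
```

## The measurement model

A free-chlorine test (a bromothymol-blue strip that turns blue, or a DPD
cuvette that turns pink) is photographed next to a printed Color QR code.
The code plays three roles at once: it identifies the assay (URL +
fragment id in the payload), anchors the scene geometrically (finder and
alignment patterns fix a projective frame), and carries a color-constancy
chart (its embedded reference patches have known colors under the
reference condition, a 6500 K illuminant). The pipeline is:

1. detect and decode the symbol; estimate the module-to-image homography;
2. rectify the photograph to a canonical frame in which the symbol
   occupies a fixed square and the assay hardware sits in a fixed window
   to its right (this placement keeps projective distortion of the assay
   region small);
3. sample each palette patch (mean over the central 50 % of its module
   square, avoiding resampling bleed at module borders) and fit the
   color-correction map from captured to reference colors;
4. locate the assay ROI — the strip's ink pad or the cuvette's inner
   square — and measure its mean color;
5. correct the mean color (mean-then-correct), derive the
   (R, G, B, H, L, S) feature vector, classify the chlorine level and,
   inside the acceptable range, convert the features to a ppm estimate.

The two final models are deliberately simple and interpretable: an RBF
support-vector machine for the 3-class decision, and a univariate
log-linear calibration for the quantitative estimate.

## Back-compatible color embedding

A version-3 symbol (29 × 29 modules) holds the payload and the chart.
Back-compatibility rests on one invariant: a palette entry may only
replace a module whose binary value matches the entry's luminance class,
where class is Rec.601 luminance 0.299R + 0.587G + 0.114B compared with
the mid-gray threshold 128. Binarizing the colored symbol at that
threshold then reproduces the black/white matrix cell for cell, and any
binary decoder keeps working; the error-correction budget is never spent
on the embedding itself. Placements are chosen greedily in row-major
order over the data region (function patterns are never colored), which
makes them a deterministic function of payload and palette — the analyzer
recomputes them from the id instead of needing a side channel.

The default error-correction level is Q. Byte-mode capacity of a
version-3 symbol is 53/42/32/24 characters at L/M/Q/H; a typical payload
(`http://diesmar.com/#n87RXv6i3`, 29 bytes) fits H only by dropping to a
shorter id, while Q holds it with the strongest remaining correction
budget (2 blocks × 18 EC codewords, up to 9 byte errors per block). Both
the level and the version are configurable.

The two shipped 24-entry palettes span the BTB yellow–green–blue ramp and
the DPD white–pink ramp, each with neutral (white to near-black) and
primary/secondary anchors so the correction map is constrained across the
RGB cube. The numeric values are package constants chosen to cover the
dye gamut — they are a design choice, not measured ground truth, and any
palette JSON with the same schema can replace them.

## Thin-plate-spline color correction

Captured palette colors $c_i$ and reference values $r_i$ are
interpolation pairs for three scalar maps, one per output channel:

$$f_k(c) = a_{0k} + a_k^\top c + \sum_i w_{ik}\,\varphi(\lVert c - c_i\rVert),
\qquad \varphi(r) = r^2 \log r,\ \varphi(0)=0,$$

solved per channel from
$\begin{bmatrix} K+\lambda I & P \\ P^\top & 0\end{bmatrix}
 \begin{bmatrix} w \\ a \end{bmatrix} =
 \begin{bmatrix} y \\ 0 \end{bmatrix}$
with $K_{ij}=\varphi(\lVert c_i-c_j\rVert)$ and $P_i=(1, c_i^\top)$. The
side conditions $P^\top w = 0$ make the radial part orthogonal to the
affine part, so affine distortions (including any diagonal white-balance)
are reproduced exactly by the affine block alone, and the radial terms
only absorb genuine non-linearity. Choices worth recording:

* **Kernel.** $r^2\log r$ (classical thin-plate basis) is the default;
  the polyharmonic $\varphi(r)=r$ is selectable. Both satisfy the
  interpolation contract; the default is smoother between control points.
* **Regularization.** $\lambda = 0$ by default: with two dozen patch
  means (each already an average over many pixels) measurement noise is
  small and exact interpolation is the behavior the quality gate
  (`correction_residual`) assumes. $\lambda > 0$ is available when
  captures are noisy.
* **Color space.** Raw 8-bit sRGB values without linearization — the map
  is fitted between captured and reference *encoded* values, so whatever
  static non-linearity the capture applied is folded into the map.
* **Mean-then-correct.** The ROI mean is corrected rather than
  correcting every pixel and averaging; with a near-affine map over the
  small within-ROI spread the difference is negligible and the cost is
  one map evaluation. Whole-image correction is still available for
  display.
* **Numerics.** The block system is solved densely (n ≤ a few dozen)
  with one iterative-refinement step; kernel distances at evaluation are
  computed by explicit differencing because the
  $|a|^2+|b|^2-2ab$ expansion cancels catastrophically near control
  points, which is visible at interpolation tolerances with the linear
  kernel. Degenerate control points (coplanar in RGB) raise an error
  rather than returning an ill-conditioned map.

## ROI detection

**Strip pad.** The pad detector is multi-scale normalized
cross-correlation (scales 0.75–1.5, acceptance threshold 0.5) of a
structural template — a darker square pad on a lighter strip background.
NCC is invariant to affine intensity changes, so the template encodes
shape rather than the concentration-dependent pad color. The detector
deliberately has the same contract (box + confidence score) as an
appearance-based cascade, so a trained cascade can be substituted without
touching the pipeline. Correlation is computed via FFT convolution for
speed. The measured region is the central ⅔ of the detected pad, keeping
the mean clear of border bleed.

**Cuvette.** The cuvette face is printed with a dark border precisely to
make detection easy. The detector thresholds the search window (Otsu),
labels connected dark components, fills their interiors, and accepts
components that are rectangular (fill ratio ≥ 0.85 of the bounding box),
have aspect ratio within ±25 % of the expected 3.0 (a 3.3 cm × 1.1 cm
visible face) and an area in range; the largest conforming component
wins and every rejection is reported with its reason. This
component-based test accepts the same set of axis-aligned dark-bordered
rectangles as a 4-vertex polygon approximation of the contour, which is
the classical formulation. The measurement ROI is the centered box 5×
smaller per axis (25× in area): big enough for a stable mean, far from
the border and meniscus.

## Colorimetric models

Class bounds are the manufacturers' intervals — low < 0.2 ppm,
acceptable to 0.9 ppm (strip) or 1.1 ppm (cuvette), excess above. The
printed intervals overlap at their endpoints, so the package uses
half-open intervals (low: C < 0.2; acceptable: 0.2 ≤ C < high; excess:
C ≥ high) to make labels deterministic.

The classifier is an RBF SVM (cost 1, bandwidth 1/d on standardized
features — d = 6 features for BTB, 2 for DPD since the pink reaction
leaves red nearly constant) trained on a stratified 80/20 split (seed 42
by default, stored with the model). Features are standardized to zero
mean and unit variance on the training split; both accuracies are logged
in the model object.

The quantitative models hold only in the acceptable range and are gated
by the classifier: BTB fits $C = m\,\ln(R_c) + b$ by ordinary least
squares (the red channel decays approximately exponentially with
concentration, so its log is linear); DPD projects $(\ln G, \ln B)$ onto
their first principal component (sign-fixed to increase with
concentration) and regresses concentration on that score. Both report
$R^2$ and 95 % confidence/prediction intervals. A regression output that
escapes the acceptable interval — which happens when the classifier was
wrong — is clipped to the interval and flagged rather than silently
reported.

Models serialize to JSON (scaler, SVM support coefficients, regression
block, bounds, split seed); a loaded model classifies through an explicit
one-vs-one decision function and regresses through the stored
coefficients. Prediction intervals need the full least-squares fit and
are not available from a loaded model.

## The synthetic generator

No photographic dataset ships with the package, so the generator is a
first-class module that emulates the acquisition conditions, with full
ground truth per scene (concentration, class, homography, ROI box,
illuminant, seed; identical seeds give byte-identical scenes).

* **Dye responses.** BTB: $R = \exp((b - C)/|m|)$ with the calibration
  constants $m = -0.64$ ppm per ln-intensity and $b = 3.3$ ppm, so the
  generator is exactly the inverse of the calibration line the analysis
  should recover; G and B decay linearly (G0 = 200, slope 25; B0 = 150,
  slope 10 per ppm). DPD: $\ln G$ and $\ln B$ decrease linearly
  ($\ln 230 - 0.35C$, $\ln 235 - 0.25C$) with R pinned at 230, giving the
  white-to-pink ramp. The channel constants besides $(m, b)$ are package
  conventions that reproduce the qualitative feature trends (monotone
  R/G/L decay, pink hue development); they are configurable and carry no
  claim of being measured values.
* **Illumination.** Von Kries diagonal gains of a Planckian radiator at
  the requested CCT (the standard cubic approximation of the locus in
  CIE (x, y), converted to linear sRGB), expressed **relative to the
  6500 K reference condition** — so gains(6500 K) ≡ (1, 1, 1) by
  construction, matching the definition of the reference palette. Two
  renderer details: the linear-light ratio is raised to 1/2.2 because
  scene pixels live on the gamma-encoded scale, and applied gains are
  divided by the largest gain, emulating camera auto-exposure so warm
  illuminants shift chromaticity without saturating bright patches
  (clipped patches would corrupt the correction chart, which real
  auto-exposed captures avoid).
* **Geometry and noise.** A projective warp with corner jitter up to a
  fraction of the canvas (default 2 %) reproduces hand-held framing
  variability; additive Gaussian sensor noise (default sd 2) comes last.
  An optional 2.2 encoding gamma supplies the per-channel non-linearity
  that separates thin-plate correction from diagonal white balance in
  tests.
* **Not modelled.** Demosaicing, lens distortion, device-specific color
  pipelines, specular reflections off the cuvette, print/ICC gamut
  errors, and the saturation channel's non-monotone behavior at high
  concentrations (in the generator it only emerges from clipping).
  Passing the synthetic suite therefore demonstrates the correctness and
  internal consistency of the pipeline under controlled distortions, not
  field performance on real phone captures.

## Problem sizes and tolerances in the test suite

The suites run at desk scale by choice: 50 seeded symbols for the
back-compatibility property; 100 response samples (noise sd 2) for
calibration recovery, accepted within the calibration line's
uncertainties (slope ±0.05, intercept ±0.2); and 200 rendered scenes
across the 2500–6500 K grid (500 K steps, 2 % warp jitter, noise sd 2)
for the end-to-end property, which requires ≥ 90 % held-out 3-class
accuracy and $R^2 \ge 0.8$ in the acceptable range. Exact contracts
(interpolation at control points, dense-solve agreement, geometry laws)
are tested at 10⁻⁶–10⁻⁸.

## Known limitations

Only planar scenes with a single symbol are supported (no curved-surface
recovery, video streams or multi-code scenes); images are read and
written as PNG (lossless is mandatory for generated references); the
decoder handles byte-mode payloads in versions 1–10; and the reference
condition is the built-in palette definition — recalibrating to a
different print run or reference illuminant means re-measuring the
palette under that condition and shipping the measured values as the
palette JSON.
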