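---
title: "Reading a colorimetric strip assay and validating it: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading a colorimetric strip assay and validating it: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaval)
```

# The measurement problem

A paper-based diazo assay quantifies total bilirubin in serum: the sample
reacts on a cellulose pad, the azobilirubin product colors the pad in
proportion to concentration, and a phone photograph of the device is turned
into a number. `chromaval` implements that reading pipeline — pad
localisation, color-space statistics, polynomial calibration — together with
the CLSI-style statistics a laboratory uses to validate such a device
(precision, detection limits, linearity, interference, predicate comparison,
stability). Because no public image set exists for devices of this kind, the
package also ships a synthetic image generator with exact ground truth; every
downstream stage is benchmarked against it.

# The synthetic device generator

The generator draws a three-pad device on a uniform body color and embeds the
true concentration, the (jittered) pad geometry, and the seed in each image.
Only the rightmost panel reacts; the other two stay at the unreacted base
color, mirroring single-panel operation of the physical device.

**Response model.** The pad color interpolates per channel between a base
(unreacted) and a target (fully developed) sRGB color with weight
$f(c) = c/(c + K)$. The true dose–response of the dye is not published
numerically, so a saturating monotone form was chosen deliberately: it is
strictly monotone (what the observed concentration gradient shows), and its
curvature exercises the linearity and detection-limit machinery more honestly
than a linear ramp would. $K$ (default 4 mg/dl, near the top of the assay's
quantifiable range so curvature over 0.5–7 mg/dl is moderate) and both colors
are configurable. The default colors — base (225, 218, 200), a pale cream,
and target (150, 60, 110), a red-violet plausible for an azo dye — are
placeholders, not measurements.

**Degradations.** Three are modelled, each the simplest member of its family:
i.i.d. Gaussian per-channel noise (SD in 8-bit units, default 4), a radial
quadratic vignette centred on the frame (default strength 0.05, emulating
LED ring lighting falloff), and uniform translation jitter of the device
within the frame (default ±10 px). Pixel values are clipped to [0, 255] and
quantised to integers after all degradations. Not modelled, by design:
camera optics, JPEG artifacts, perspective, reaction kinetics (images are
end-point), and spatial development gradients within a pad. Tests passing on
these images therefore demonstrate correctness of the algorithms, not
robustness to every failure mode of real phone photographs.

**Determinism.** A master seed spawns one seed per image through a fixed
affine-mod rule, so any subset of a calibration set can be regenerated
byte-identically.

# Pad localisation

The detector follows a standard segmentation recipe: luma grayscale, Otsu
threshold (pads are darker than the device body), connected-component
labelling, then filtering by area (within 0.3–3× the expected pad area) and
bounding-box aspect ratio (1.0–1.6, around the pads' 7.5:6 shape). Survivors
are ordered left to right and the requested panel's box is reduced to its
central 60% — edges and wicking artifacts at the pad boundary carry little
assay information and hurt the statistics.

One amendment to the plain recipe proved necessary. The image histogram is
trimodal (body, blank pads, developed pad), and when the developed pad is
strongly colored, the two-class Otsu threshold can fall *between* the
developed pad and the blank pads, so only one component survives and
left-to-right indexing breaks. When fewer than three candidates are found the
detector re-thresholds the brighter class (a second-level Otsu), which
separates blank pads from the body and restores all three candidates. With
this amendment the detector recovers the true pad interior with IoU ≥ 0.8 on
randomized synthetic images across the full concentration range at noise SD
up to 8 (measured at 200/200 in the test suite).

Coordinates are 0-based and half-open everywhere in the package.

# Color features

Each ROI patch is duplicated into RGB, XYZ, LAB and HSV, and mean, median and
histogram mode are computed per channel: 4 × 3 × 3 = 36 features named
`SPACE_channel_stat` (e.g. `LAB_0_mean`). Conversions use the standard sRGB
linearisation with D65 white (`grDevices::convertColor`), hue is reported in
degrees with achromatic pixels assigned hue 0, and L\* spans 0–100. The mode
of a continuous channel is ill-defined without binning, so it is taken over
256 uniform bins across the channel's nominal range, ties resolved toward the
lower bin; on native 8-bit channels the bins coincide with the levels, so the
mode is the most frequent level itself.

# Calibration

The production constraint for devices of this class is a low-order (< 4)
polynomial on features from a single color space, not using all features of
that space. `chromaval` therefore fits candidates that are polynomials of
**one scalar feature** each, searches all 36 features × orders 1–3, and picks
the candidate with the highest R² on a held-out validation set (default
60/40 split, stratified by concentration). Ties are broken toward the lower
order, then toward the earlier space in the fixed order RGB, XYZ, LAB, HSV.
Two open choices were resolved as follows:

* *Forward regression.* Concentration is regressed on the feature (rather
  than inverting a feature-on-concentration fit). A cubic comfortably
  absorbs the mild nonlinearity that the saturating response induces over
  the quantifiable range.
* *Reporting.* Predictions are floored at 0 mg/dl and returned at full
  precision; the 2-decimal display convention is applied only at
  presentation. Values outside the quantifiable range 0.5–7.0 mg/dl are
  flagged, not clipped, so detection-limit studies below 0.5 mg/dl keep
  their information.

On synthetic sets (10 levels × 10 replicates, noise SD 4), the selected
model's validation R² exceeds 0.98 — the suite measures ≈ 0.9998 — and
remains ≥ 0.999 on noiseless images, where the floor is set by 8-bit
quantisation plus the polynomial approximation of the response inverse.

# Precision (EP05)

Two balanced two-fold nested layouts are supported: site → day → replicate
(multi-site reproducibility) and day → run → replicate (single-site).
Mean squares come from the standard balanced nested sums of squares, and the
variance components from the method-of-moments identities

$$V_{error} = MS_{error},\qquad
  V_{day} = \frac{MS_{day} - MS_{error}}{n_{rep}},\qquad
  V_{site} = \frac{MS_{site} - MS_{day}}{n_{rep}\, n_{day}}$$

(and analogously $V_{run} = (MS_{run}-MS_{error})/n_{rep}$,
$V_{day} = (MS_{day}-MS_{run})/(n_{run} n_{rep})$ for the single-site
layout). Negative estimates are truncated to zero per CLSI convention, with
a flag; the untruncated values are kept alongside because the truncated
estimator is biased upward for small components, which matters when checking
estimator calibration by simulation. Precision tiers are
repeatability $\sqrt{V_{error}}$, within-laboratory
$\sqrt{V_{error}+V_{day}}$ (plus $V_{run}$ single-site), reproducibility
$\sqrt{V_{error}+V_{day}+V_{site}}$; %CV is computed from the *unrounded*
SD and the reported mean — published tables that round components before
deriving SDs cannot always be reconciled with themselves, and full-precision
arithmetic avoids importing that inconsistency. Only balanced designs are
accepted (unbalanced data get a pointed error naming the offending cell);
REML for unbalanced designs is out of scope.

# Detection limits (EP17)

The limit of blank is nonparametric: with $B$ blanks and percentile
$p$ (default 0.95, from a 5% Type I risk), the rank position is
$0.5 + B\,p$; fractional positions are linearly interpolated between the
bracketing order statistics. The reported LoB across reagent lots is the
maximum. Outlier exclusion is manual and recorded with reasons — no
automatic rejection rule is invented.

The limit of detection combines the blank limit with low-level spread:
$LoD = LoB + c_p\, SD_L$, where $SD_L$ is the df-weighted pooled SD of the
low-level samples and $c_p = z_{0.95}/(1 - \tfrac{1}{4\,df})$ with
$df = N - K$ is the 95th-percentile multiplier with the standard
small-sample correction. The bare form $c_p\,SD_L$ without the blank term is
also exposed (`formula = "bare"`) because it appears in some write-ups, but
it is not the default: it ignores the blank distribution and is not
consistent with the parametric EP17 construction. Pooled SDs are used
unrounded; rounding before combining visibly changes the second decimal of
the LoD.

# Linearity (EP06)

Polynomials of order 1–3 are fit to replicate-level measurements against
assigned concentrations (replicates as individual points — with 7 levels in
duplicate this yields residual dfs 12/11/10). The nonlinear coefficients
(b2; b2 and b3) are screened against the two-sided Student-t critical value
at α = 0.05 (2.228 at 10 df). The practical-significance check compares
first- and second-order predictions per level with
$\%\Delta = 100\,(p_2-p_1)/p_2$ — the second-order prediction is the
denominator, the convention that reproduces the published percent
differences — against a 20% laboratory criterion. The system is linear when
the quadratic coefficient is not significant or all $|\%\Delta|$ are below
the criterion.

# Interference (EP07), comparison (EP09), stability (EP25)

**Interference** is a paired screen: $d_{obs}$ is the test-minus-control mean
difference, expressed as a percentage of the control mean (normalising by
the control mean rather than the nominal analyte level — the choice that
makes the flag scale-invariant). Substances at or above 10% are flagged;
the boundary convention (exactly 10% flags) is configurable. The default
panel carries the six recommended serum interferents at their standard test
concentrations, each at analyte levels 0.4 and 2.0 mg/dl. A linear
interpolation helper estimates the dose at which interference crosses the
threshold between two tested doses; it is an extension, not part of the
screen.

**Comparison** against a predicate analyzer uses predicate − test
differences. The bias point estimate is the sample median (the difference
distribution is typically skewed); its 95% CI is the distribution-free
signed-rank interval from ordered Walsh averages — exact signed-rank
critical values for n ≤ 25, normal approximation above, zero differences
dropped before ranking. Equivalence holds when the whole CI sits inside
±0.1 mg/dl (closed interval), and per-sample CLIA acceptability uses the
±0.4 mg/dl total-bilirubin allowance, boundary inclusive. Simulation in the
test suite confirms ≈ 95% coverage of the interval at n = 57.

**Stability** screens each timepoint against week 0 with a Welch two-sample
t-test per concentration, α = 0.05, no multiplicity correction by default
(matching per-week reporting conventions; a Bonferroni option exists).
Degenerate zero-variance cases are pinned: identical constant arms give
p = 1, constant-but-different arms p = 0.

# Numerical conventions and problem sizes

Full-precision values are authoritative throughout; display rounding
(SD at 3 decimals, %CV at 1, concentrations at 2) is applied only in report
formatting. Model selection treats validation-R² differences below 1e-12 as
ties. The simulation sizes used by the test suite — 200 randomized images
for the detector, 10 × 10 images per calibration run, 200 seeds for
variance-component recovery, 1000 replicates for CI coverage, 500 blank
panels for the LoB check — were chosen as the smallest sizes at which the
Monte-Carlo error is comfortably below the property margins being asserted.

# Known limitations

* The generator's defaults describe a plausible device, not a measured one;
  absolute feature values carry no physical meaning, only their relationship
  to concentration does.
* The ROI detector assumes one device per frame, roughly axis-aligned pads,
  and a body brighter than the pads; perspective correction and barcode
  handling are out of scope.
* Precision analysis requires balanced designs.
* The published regression coefficients of the original linearity table and
  the raw comparison pairs are not recoverable from printed summaries, so
  those exact numbers are not test anchors; the package reproduces the
  published *derived* quantities (critical values, dfs, detection limits,
  precision arithmetic) and validates the rest by construction against its
  own generator.
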