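---
title: "Methods: bead segmentation and affinity quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead segmentation and affinity quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadpull)
```

## The assay and its measurement model

A bead pull-down couples a binding step (bait immobilized on ~30 µm or
~90 µm glutathione agarose beads, incubated with lysate containing a
GFP-fused prey) to an imaging readout: washed beads are photographed under
an epifluorescence microscope and the retained prey is quantified directly
from the pixels. Two properties make the readout quantitative. First, a
scientific CCD is linear in photon flux, so bead intensity is proportional
to retained prey and to exposure time. Second, over the assay's working
range the retained prey is close to linear in both bait density on the
beads and prey concentration in the lysate. The affinity statistic divides
all three factors out:

$$a_i = \frac{I_i / t_{\mathrm{exp}}}{P \cdot B}$$

per bead $i$, with $I_i$ the corrected mean bead intensity,
$t_{\mathrm{exp}}$ the exposure (ms), $P$ the prey input (exposure-normalized,
mock-corrected mean lysate fluorescence) and $B$ the bait input (an
externally semi-quantified density, µg/µl or µM, treated as an opaque
positive scalar). Within a comparison set the values are plotted relative
to the largest, scaled to 100; when a set shares the same bait or prey,
that input is set to 1 and only relative comparisons are meaningful. The
statistic is deliberately unitless up to a shared constant: any constant
factor cancels in every ratio the assay reports (fold changes, relative
affinities).

Per-bead affinities are computed first and then averaged — not the other
way round — because the per-bead spread is the error model: it feeds the SD
bars, the bead count *n*, and the Welch t-tests between conditions.

## Pipeline and parameter choices

`quantify_image()` runs four stages. All defaults below are the assay's
standard recipe and are exposed through `pipeline_params()` / YAML configs.

**Gaussian denoising** (`gaussian_radius_px = 1`). The "radius" is
interpreted as the Gaussian σ in pixels, kernel truncated at 4σ and
renormalized. The interpretation of an ImageJ-style blur "radius" is not
standardized; σ = radius is the simplest faithful reading, and the
parameter is config-overridable.

**Rolling-ball background subtraction** (`ball_radius_px = 400`). The
background is the lower envelope traced by a ball rolled beneath the
intensity surface — grayscale opening with a spherical-cap structuring
element whose heights share the intensity axis. Exact opening is O(r²) per
pixel, prohibitive at r = 400, so above r = 64 the image is shrunk by
block-minimum downsampling (factor ⌈r/32⌉), opened at the proportionally
smaller radius, and restored by bilinear interpolation. Two details
matter:

* *Slope removal.* With a steep illumination ramp the ball's contact point
  for a given pixel can lie outside the field; clipped windows then bias
  the envelope low near borders. A robust plane (least squares, refit on
  the lower half of residuals so beads cannot tilt it) is subtracted
  before opening and added back after. Opening a slope-free residual has
  only local contacts, and a plane passes through opening unchanged, so
  flat and tilted fields are handled identically.
* *Envelope cap.* The interpolated background is capped at the observed
  image, so `background ≤ image` holds exactly and corrected values are
  never negative by construction of the envelope (they are additionally
  clipped at 0 — negative fluorescence is non-physical).

The fast path is validated against brute-force ball opening at radii ≤ 16,
where the two must agree to within one camera unit.

**Segmentation.** Otsu's between-class-variance threshold on the corrected
image by default (deterministic, parameter-free; a manual threshold is
available — on a two-level image the criterion has a plateau of equivalent
optima, so tests compare attained variance, not the raw threshold value).
Foreground connectivity is 8-connected. Touching beads are separated by
watershed on the Euclidean distance transform with shallow maxima
suppressed at depth 1 px (h-maxima, h = 1), which splits genuine pairs but
never fragments an isolated convex disk; 1-px split lines are carved out
as background so masks never share pixels.

**Particle validation** (area ≥ 200 px², circularity 0.60–1.00, edge
particles excluded). Circularity is 4πA/P² capped at 1, and is only
reproducible together with a perimeter convention: here the traced-boundary
estimator of the reference software for this assay — Moore chain steps
weighted 0.948 (straight) and 1.340 (diagonal). Under this convention a
rasterized 30-px-radius disk scores ~1.0 and beads with 10% diameter
dispersion stay far above the 0.60 cut. Aggregated bead clumps are removed
implicitly: after watershed their fragments are non-circular. Rejections
are recorded with the first failing rule in the order size → circularity →
edge, and edge contact is judged on the particle's own pixels after
watershed, so a cleanly split interior bead survives even when its former
neighbour touched the border. A note on elongated fixtures: a smooth 3:1
ellipse has true circularity ≈ 0.66 and legitimately *passes* the 0.60
cut; the suite's circularity-rejection object is therefore a 4:1 ellipse
(true circularity ≈ 0.54).

**Measurement corrections.** Bead means are taken on the
background-subtracted image, then corrected twice: by the residual
background (mean of corrected pixels outside all masks dilated by 3 px) and
by a scalar blank-bead autofluorescence. The residual term exists because
the rolling-ball background is a lower envelope: after subtraction the
empty field averages ~2.3 smoothed-noise SDs above zero, an additive offset
that would otherwise break affinity constancy across an input grid.
Negative corrected means floor at 0 with an audit flag. Beads containing
saturated pixels (2^bit_depth − 1) break linearity and are excluded by
default (`saturation_policy`, overridable). The signal-to-noise ratio is
the mean over bead pixels divided by the SD over background pixels, where
"background" is the complement of the masks dilated by 3 px — the dilation
keeps the dim corona around beads out of the noise estimate.

## The synthetic data generator

`render_scene()` emulates the acquisition: a 1040 × 1392 px field at
0.5 µm/px (0.7 × 0.5 mm field of view), 50–200 beads per field, bead
diameters normal around the nominal 30 µm (or 90 µm) with 10% CV truncated
at 3 SD, uniform disk profiles for small beads and a peripheral-bright
"halo" profile for large ones — modeled linearly, I(r) = I_c +
(I_rim − I_c)(r/R) with rim/center ratio 3, the simplest testable form of
the qualitative rim-bright description (prey diffusion into large beads is
limited). Pixels are background + illumination (planar tilt or radial
vignette) + signal + additive Gaussian noise, quantized and clipped to the
camera bit depth. The default noise SD is signal/4: the hardest reported
operating regime (SNR ≈ 4). Identical spec + seed gives bit-identical
images, and the ground truth (label map, per-bead exact mean signal) is
computed from the rendered raster itself.

Defaults worth stating explicitly:

* `touching_fraction = 0`: the end-to-end recovery benchmark is defined on
  non-touching fields; touching pairs are a generator option exercised by
  the watershed tests, because watershed-carved split lines can shift a
  centroid by ~2 px and would make the recovery metric ambiguous.
* Beads are placed fully interior (margin ≥ radius + 1): in real images
  the edge rule removes partially imaged beads; in synthetic recovery
  metrics it must not remove ground-truth beads.
* Quantization can be disabled (`quantize = FALSE`): a zero-background
  noise field clipped at 0 becomes half-normal (SD ≈ 0.6σ), so tests of
  noise statistics use the float render.

`simulate_assay_series()` builds a full input grid (default: bait 3, 6,
9 µg/µl × four prey levels spanning 6-fold — the assay's characterization
design) with true per-ms bead intensity = affinity × bait × prey,
per-bead lognormal brightness variation (default CV 15%, a free parameter:
real between-bead dispersion is visible in reported SDs but not
parameterized), and per-condition lysate/mock well images. By default each
condition's exposure is chosen so the expected bead intensity lands at
~2000 camera units, mirroring how exposures are adapted at the microscope
to fill the camera's dynamic range — which is exactly the variation the
affinity statistic must cancel, so the default exercises it.

What the generator does *not* emulate: Poisson photon statistics (additive
Gaussian only), optics-level PSF blur, 3-D bead structure, phase-contrast
rendering, bead aggregates, and debris. Passing tests therefore demonstrate
the pipeline's correctness and its noise robustness in the stated regime,
not performance on real micrographs with structured artifacts.

## Numerical choices and degenerate inputs

* SDs use the n−1 denominator everywhere (the spreadsheet convention the
  assay's statistics follow); p-values are reported at full precision with
  no multiple-testing correction (pairwise tests only).
* Welch's test: unequal-variance t with Welch–Satterthwaite df, two-tailed.
  Identical samples give t = 0, p = 1; two zero-variance samples are an
  error.
* Linear fits: OLS; constant y over varying x returns slope 0 and R² = 0 by
  convention; constant x is an error.
* Relative affinities are computed ratio-first (100 · mean/max) so the
  maximum is exactly 100 in floating point.
* Uniform images have no Otsu threshold ("no bimodal separation" error;
  fall back to manual). Empty masks yield empty label maps, not errors;
  a batch run that retains zero particles exits with a diagnostic.
* Otsu ties and watershed seed ties resolve deterministically (lowest
  index); labels are compacted to 1..K in column-major first-appearance
  order, so identical inputs give byte-identical outputs.
* 12-bit cameras writing 16-bit containers are accepted; `bit_depth` is
  caller metadata with a max-value sanity check (warning, not error).
  Exposure times are caller/config metadata, never parsed from TIFF tags.
  PNG containers are 8-bit only; deeper data must use TIFF.

## Problem sizes used by the test and acceptance runs

The recovery benchmark uses ten full-size fields with 50–200 beads; the
input-grid benchmark uses 12 conditions of ~100 beads on full-size fields;
background-oracle checks use 128 × 128 images at radii ≤ 16, where exact
opening is cheap. Unit tests use 300–500 px fields, which hold ~10 beads —
the per-bead measurement and statistics do not depend on field size.

## Known limitations

* Bait input is an external semi-quantified scalar; the package does not
  densitometer gels, and cross-assay comparison requires consistent bait
  units (unit tags are compared with a warning only).
* The affinity is relative, not an equilibrium constant: no K_d, no
  binding model, no saturation analysis.
* Very dim beads that the threshold misses entirely have no automated
  fallback (the interactive manual-mask route is out of scope).
* The rolling-ball fast path assumes illumination varies smoothly at the
  shrink scale (~r/32 px); pathological high-frequency illumination would
  alias into the block minima.
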