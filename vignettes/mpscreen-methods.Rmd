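---
title: "Methods: screening Nile-red-stained filters for microplastics"
author: "mpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening Nile-red-stained filters for microplastics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpscreen)
```

## The screening problem

Digesting edible seafood tissue and filtering the digestate leaves a
membrane carrying both microplastic (MP) particles and particles of
natural origin (PNO) — fishbone fragments, chitin, shell debris,
cellulose fibres. After staining with the solvatochromic dye Nile red,
both kinds fluoresce, but differently: well-stained polymers are bright
with a characteristic red-dominated emission, while most matrix
particles stay dim or off-colour. `mpscreen` turns a calibrated RGB
fluorescence scan of such a filter into a per-particle table and a
blank-corrected MP count and mass estimate per sample, replacing
interactive image editing with a deterministic, fully recorded chain:

1. optional maximum projection of a z-stack (`maxProject()`),
2. global brightness thresholding (`binarize()`),
3. optional morphological opening (`cleanMask()`),
4. 8-connected labelling with a minimum-area filter
   (`labelParticles()`),
5. per-particle morphometry and fluorescence features
   (`measureMorphology()`, `measureFluorescence()`),
6. rule-based classification and size-class binning
   (`classifyShape()`, `classifyFluorescence()`, `assignSizeClass()`),
7. volume and mass estimation (`estimateVolume()`, `estimateMass()`),
8. aggregation and procedural-blank correction (`aggregateSample()`,
   `computeLoq()`, `blankCorrect()`).

`runSample()` and `runSeries()` orchestrate the chain; every report
carries the threshold used, per-stage particle counts and a
configuration hash.

## Features and their definitions

**Brightness.** The per-pixel brightness is `max(R, G, B)` on the 8-bit
scale. The total particle brightness (TPB) is the mean brightness over
the particle's pixels. This definition reproduces the magnitudes
reported for reference polymers (roughly 25 for weak alcohol staining up
to ~90 for optimal staining) and is the package's primary intensity
feature; a mean-luminance variant would be a drop-in alternative, and
the choice is deliberately confined to one helper so it can be swapped.

**Colour.** Channel means over the particle footprint are reduced to
colour fractions `mean_r / (mean_r + mean_g + mean_b)` (and likewise for
green and blue), which sum to one for any non-black particle and are
insensitive to overall intensity.

**Morphometry.** Area is the pixel count times the squared pixel pitch —
an exact invariant used as a test oracle. The maximum Feret (caliper)
diameter is measured over the convex hull of the pixel *outlines*
(pixels modelled as unit squares): it equals the true diagonal for
rectangles and is exact for convex digitised shapes, whereas a
center-to-center measurement systematically loses one pixel. The
perimeter is a Cauchy–Crofton estimate from foreground/background
transition counts along four scan-line families; it is exact for
digitised discs and about 5% low for axis-aligned squares. Ellipse axes
come from second central moments (each pixel contributing its own 1/12
unit-square moment, so a single pixel has aspect ratio 1); circularity
`4*pi*A/P^2` is clipped at 1 to absorb discretisation overshoot on small
discs.

## Segmentation choices

The binary mask is produced by a global Otsu threshold on the brightness
histogram plus a signed user offset, with an explicit-threshold
override. This replaces manual brightness/contrast editing: it is
deterministic, recorded in the mask, and monotone (raising the threshold
never adds pixels).

Connectivity is fixed at 8 neighbours. The default minimum component
area is 2 px, which at the 5 µm/pixel pitch of a 5x objective scan puts
the reliable detection floor at ~10 µm, matching the optical resolution
of the acquisition.

`cleanMask()` implements the classical binary opening used to delete
isolated-pixel artefacts. The default pipeline, however, leaves opening
off (`opening_radius = 0`) and removes isolated pixels through the
minimum-area filter instead: a 3×3 opening also erases genuine 2–8 px
particles, which at coarse pixel pitches are exactly the smallest size
classes the screen should retain. Opening remains available for noisy
scans where a stronger cleanup is worth the loss of the smallest
detections.

## Classification and quantification

Particles are classified on two independent axes:

* **Shape** — fibre if the fitted-ellipse aspect ratio is ≥ 3, spheroid
  if circularity ≥ 0.85 and aspect ratio ≤ 1.3, fragment otherwise.
* **Fluorescence** — weak (TPB ≤ 40), medium (≤ 75) or bright;
  MP-suspect requires TPB ≥ 45 *and* a red fraction inside
  [0.34, 0.80].

All cuts live in `classifierConfig()` and serialise to YAML. The
defaults are re-derivations chosen so that brightly and medium-stained
polymer distributions pass while weakly stained and off-colour natural
material fails; they are not published constants, and laboratories with
different optics should re-tune them on reference particles.

Size classes on the maximum Feret diameter are 5–10, 10–50, 50–100,
100–500, 500–1000 and 1000–5000 µm, lower-inclusive and
upper-exclusive, with the top class closed at 5000 µm; sub-5 µm
particles are labelled below-range and excluded from MP totals (they sit
below the reliable detection floor).

Volumes use three parameter-free solids: spheres on the area-equivalent
diameter for spheroids, cuboids of major × minor × minor for fragments
(the height factor defaults to 1 and is configurable), and cylinders of
length = major axis, diameter = minor axis for fibres. Mass is volume ×
density × 1e-6 µg, with a small polymer density table and a 1.05 g/cm³
fallback for unknown composition, since polymer identity cannot be
inferred from Nile-red fluorescence alone.

## Blank correction

Each sample series carries procedural blanks (typically three). For
every category — size class × shape × fluorescence group — the blank
counts and masses give a mean and sample SD (n − 1 denominator; SD = 0
for a single blank), and a limit of quantification LOQ = mean + 10 × SD.
A sample category above its LOQ is corrected by subtracting the blank
mean (floored at zero); a category at or below the LOQ is *censored*:
it reports zero with a flag, rather than the LOQ value, which keeps the
report conservative. Counts and masses are corrected independently with
the same 10×SD multiplier. Without blanks, `runSeries()` reports
uncorrected results with a warning rather than refusing to run — a
deliberate screening-usability choice.

## The synthetic-filter generator

Offline validation needs images with known truth. `samplePopulation()`
draws particle parameter records from class specifications (shape
mixture; log-normal sizes truncated to 5–5000 µm; truncated-normal TPB
and red fraction), and `renderFilterImage()` rasterises them onto a
noisy dim background (per-channel Gaussian noise, default mean 8,
SD 3 — a calibration-free choice, since no numeric background levels are
published for seafood matrices) as rotated ellipses, rectangles and
capsules. Per-pixel particle brightness is drawn around the particle's
TPB and the channels are scaled so the rendered TPB and red fraction
match the generating parameters. Well-separated placement uses a
shuffled grid whose cell size guarantees the requested gap, so
footprints are provably disjoint; an impossible request fails loudly.
Diffuse low-contrast matrix-residue patches can be added at a configured
density (off by default). Every generator output is a pure function of
its seed and spec, with a single stream consumed in documented order.

The packaged reference population (`referenceFixtureSet()`) contains six
bright-to-medium MP classes and four weak/off-colour PNO classes
(fishbone, chitin, mussel shell, cotton), 100 particles each. Its
numeric parameters are synthetic assumptions, fixed once in
`inst/extdata/reference_population.yaml`: MP classes are placed so that
roughly 1% of each class falls below the MP cuts, and chitin — the
closest natural confounder — contributes about 1% false positives.
On this fixture the default classifier reaches ~99% accuracy with
per-polymer miss rates within 4%, consistent with the high-90s accuracy
regime reported for threshold-based MP identification of optimally
stained, non-aged, pigment-free reference particles.

What the generator does *not* emulate — and what passing tests therefore
do not show — includes: particle agglomeration and touching particles,
solvent-induced particle merging, uneven staining within a particle,
pigmented/aged polymers with suppressed fluorescence, high and spatially
structured matrix autofluorescence, and optical effects (point-spread
blur, vignetting, chromatic aberration). Real-sample performance
additionally depends on digestion quality and staining chemistry, which
are outside the package's scope.

## Numerical conventions and degenerate inputs

* Thresholding uses strict `>` against the effective cut; the Otsu
  histogram has 256 levels.
* Components are returned in raster order (component containing the
  first foreground pixel in row-major scan order first), so outputs are
  stable across runs.
* A single-pixel particle has aspect ratio 1, Feret √2 px, and positive
  area; empty components, out-of-bounds footprints, non-positive pixel
  sizes, densities or diameters, and threshold values outside [0, 255]
  raise errors rather than propagating NaN.
* An entirely black particle has undefined colour fractions (`NA`) and
  is never MP-suspect.
* Truncated distributions whose windows carry essentially no mass (for
  example a TPB mean far outside [0, 255] with a tiny SD) are
  configuration errors.

## Problem sizes used for validation

The shipped test-suite exercises the full chain at desk scale: rendered
images up to 1024×1024 px, populations up to 200 rendered particles
(1000 for the feature-level fixture set), 10 fixture seeds for the
classifier accuracy check, and 500 simulated blanks for the
law-of-large-numbers LOQ check. These sizes were chosen so the complete
suite runs in well under a minute while keeping sampling noise
comfortably inside the asserted tolerances (e.g. two-sample KS < 0.15 at
n = 200).

## Known limitations

* Rule-based thresholds are optics- and protocol-specific; the defaults
  document a structure, not a universal calibration.
* Mass estimates inherit the 2D→3D shape approximation and the assumed
  density; for mixed-polymer samples they are order-of-magnitude
  screening values.
* Touching particles are not split (no watershed); heavily loaded
  filters should be diluted or re-filtered.
* Fibres thinner than one pixel are rendered and measured at one-pixel
  width, biasing their volume upward.
* The 16-bit/HDR path, tile stitching and flat-field correction are out
  of scope.
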