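---
title: "Methods: multispectral staging of cutaneous squamous cell carcinoma"
author: "msiStage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral staging of cutaneous squamous cell carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`msiStage` implements an image-analysis pipeline for multispectral
microscopy (MSI) of H&E-stained skin sections, aimed at making the
histopathological staging of cutaneous squamous cell carcinoma (cSCC)
quantitative.  A 13-band acquisition (narrow-band LED illumination across
420--680 nm) gives each stained structure a characteristic per-band
contrast: hematoxylin-stained chromatin absorbs strongly around 560 nm
with a shoulder that keeps nuclei dark at 630 nm, while eosin-stained
collagen, cytoplasm and keratin absorb most strongly near 518/528 nm and
more weakly near 600 nm.  Three working bands carry the diagnostic
signal:

* **520 nm** -- eosinophilic matrix: collagen fibers in normal dermis,
  diseased epidermis in tumors;
* **600 nm** -- high-contrast round objects: unstained lipid droplets in
  normal tissue, keratin pearls in tumors;
* **630 nm** -- nuclei, via the hematoxylin red shoulder.

The pipeline chains: frame averaging, illumination correction,
feature-based mosaic stitching, band-specific segmentation, pseudo-color
composition, and three staging statistics (window-level
nucleo/cytoplasmic ratio, nuclear-atypia fraction, keratin-pearl
morphometry) compared across grades with Student's t-tests and ROC/AUC.

Because no public multispectral cSCC dataset exists, every stage is
validated against a synthetic 13-band phantom generator with pixel-level
ground truth; the generator is first-class, tested code.

# The phantom generator

## Optical model

Scenes are rendered through Beer--Lambert absorption,

$$I_\lambda(x,y) = I_0 \, V(x,y)\, 10^{-\left(c_H(x,y)\,\varepsilon_H(\lambda)
 + c_E(x,y)\,\varepsilon_E(\lambda)\right)},$$

with $I_0$ at 90 % of the sensor range, $V$ a radial vignette (1 at the
center, $1-s$ at the corners, default strength $s = 0.3$), and
per-pixel dye concentrations $c_H, c_E$.  The absorbance curves are
Gaussian models anchored at the published peaks: hematoxylin
$\varepsilon_H$ is a unit-amplitude Gaussian at 560 nm (width 60 nm),
eosin $\varepsilon_E$ an equal mixture of Gaussians at 518 and 528 nm
(width 35 nm, amplitude 0.6 each); outside the dyes' supports
(400--600 nm and 450--650 nm) values below $10^{-3}$ are truncated to
zero.  Two notes on this choice:

* the two eosin component peaks are 10 nm apart with 35 nm widths, so
  the mixture is effectively unimodal on any 20 nm band grid -- the
  model encodes the published peak *positions*, not a resolvable
  double peak;
* absolute amplitudes are arbitrary.  Only the relative band contrast
  matters for segmentation, which is also why the working-band logic
  survives the approximation.

Each acquisition frame adds independent Gaussian sensor noise (default
sd 2 gray levels at 8 bit), clipped to the valid range; five frames per
field are averaged, which reduces noise by $\sqrt 5$.

## Band centers

Only the spectral range (420--680 nm) and bandwidth (20 nm) of the
13-LED instrument are published; the exact centers are not.  A uniform
20 nm grid starting at 420 nm cannot contain the 630 nm working band,
so the package fixes its own convention, `defaultBandCenters()`:
420, 440, ..., 600, 630, 660, 680 nm -- thirteen centers spanning the
range that include all three working bands.  Every function accepts
arbitrary strictly increasing center lists.

## Tissue geometry per grade

`gradeParams()` encodes the qualitative histology of the three classes:

| parameter | normal | poorly diff. | well diff. |
|---|---|---|---|
| nucleus density (mm⁻²) | 50 | 4000 | 2500 |
| nuclear area (µm², lognormal) | ln 15, sd 0.25 | ln 32, sd 0.45 | ln 14, sd 0.30 |
| keratin pearls / field | 0 | 0.5 | 4 |
| lipid droplets / field | 3 | 0 | 0 |
| squamous pits / field | 0 | 0 | 2 |
| matrix coverage | 0.75 | 0.88 | 0.85 |

Counts are Poisson draws; nuclei are non-overlapping ellipses placed by
rejection sampling (100 tries, dropped with a warning on failure; an
`allowContact` flag permits touching nuclei for watershed testing);
pearls are disks with concentric eosin-dense rings; droplets and pits
are unstained clear disks.  The matrix is a thresholded smooth Gaussian
random field, giving collagen a fibrous texture at a 5 px correlation
scale and tumor epidermis a coarser 8 px texture.

The nuclear-area lognormals implement the atypia contrast (poorly
differentiated nuclei are larger and more variable, so a *smaller*
fraction falls below 20 µm²).  The tumor densities follow typical
carcinoma cellularity: tumor nests are confluent cellular sheets, and
at 2500--4000 nuclei/mm² a 200 × 200 px window (100 × 100 µm at the
default 0.5 µm/px) contains tens of tumor nuclei against at most a few
dermal fibroblasts.  This margin is what makes the window-level
nucleo/cytoplasmic ratio separate normal from tumor tissue *by
construction* -- at densities an order of magnitude lower, Poisson
fluctuations of the per-window count would overlap the normal windows'
upper tail and the designed separation would be a coin toss.  The
within-tumor comparison (poorly vs well) is deliberately *not*
separable on the NC ratio with these defaults; the atypia fraction is
the statistic that separates the tumor grades.

# Preprocessing

`averageFrames()` is the per-pixel arithmetic mean of the repeated
acquisition frames (kept in floating point).  `correctIllumination()`
estimates the illumination field $L$ as a wide Gaussian blur of the
normalized band (default $\sigma = \max(H,W)/8$; the blur runs on a
decimated image since $L$ is smooth by construction) and re-exposes
each pixel through its own gamma,

$$O = I_{\mathrm{norm}}^{\gamma(x,y)}, \qquad
\gamma(x,y) = \frac{\log m}{\log L(x,y)}, \qquad m = \operatorname{mean}(L).$$

This per-pixel 2-D gamma map brightens illumination deficits and
darkens excesses; it maps a pure flat field exactly onto its mean, is
the identity on uniform images ($\gamma \equiv 1$), and is contractive
(a second application changes the image less than the first).  $L$ is
clamped to $[10^{-4}, 1-10^{-4}]$ to keep the exponent finite.
Averaging precedes correction, matching the acquisition protocol; the
two orders differ only at second order in the noise.

# Stitching

Overlapping fields are mosaicked by feature matching: corner keypoints
(Harris response on a lightly smoothed image, 5 × 5 non-maximum
suppression) with z-normalized 15 × 15 intensity-patch descriptors,
matched by nearest descriptor distance under the Lowe ratio test
(0.75).  Pairwise transforms are estimated by RANSAC (default
similarity model -- translation, rotation, isotropic scale -- 2 px
inlier threshold, up to 2000 iterations) followed by a least-squares
refit on the inliers.  Fewer than 8 surviving matches is an error
("insufficient overlap/texture").

Registration is estimated once per tile pair on a reference band
(630 nm, where nuclear contrast is highest) and the *same* transform
is applied to all 13 bands, so the spectral cube can never develop
per-band drift.  Acellular dermis is nearly featureless at 630 nm, so
`stitchStrip()` falls back to 520 nm (maximal collagen contrast) when
the reference band lacks texture.  Overlaps are fused by
distance-to-edge feathering and the mosaic is cropped to the maximal
interior rectangle free of unfilled pixels (iterative trimming of the
boundary line with the most holes).

The keypoint detector is single-scale: a motorized-stage strip has no
scale change between tiles, and the similarity model absorbs the small
rotations that occur.  Full scale-space feature pyramids are outside
the package's scope.

# Segmentation

* **520 nm and 600 nm** -- `segmentAdaptive()`: a pixel is foreground
  when it deviates from the local mean over a `blockSize` window
  (default 51 px) by more than `offsetFrac` of the image range
  (default 2 %), followed by a radius-1 opening and removal of
  components under 30 px.  Expressing the offset as a range fraction
  makes the mask invariant to affine intensity rescaling.  Stained
  structures are absorbing, so the default polarity is *dark*; for
  normal tissue at 600 nm the polarity flips to *bright* because lipid
  droplets are unstained vacuoles.  Bright candidates are further
  restricted to the filled tissue interior and to large round
  components (area ≥ 300 px, isoperimetric circularity ≥ 0.5), which
  separates droplets from irregular inter-fiber gaps that share their
  spectrum.
* **630 nm** -- `trainNucleusRF()` / `segmentNuclei()`: a
  100-tree probability random forest (depth ≤ 12, balanced subsample
  of ≤ 50 000 pixels per class, fixed seed) over a fixed, versioned
  feature vector: raw 630 nm intensity, Gaussian-smoothed 630 nm at
  σ = 1, 2, 4 px, gradient magnitude (σ = 2), local 5 × 5 standard
  deviation, and the raw 520/600 nm intensities.  Training labels come
  from phantom ground truth; for real data a user-supplied annotation
  mask takes the same code path.  The probability map is thresholded
  strictly above 0.5, holes are filled, and components under 30 px
  removed.
* **Instances** -- `splitInstances()`: distance-transform watershed
  with a 2 px tolerance (h-maxima style marker merging); masks without
  internal maxima degrade to connected components.
* **Squamous pits** -- enclosed holes of the segmented tissue at least
  200 px in area, evaluated for the well-differentiated grade only.
  This is a minimal operationalization: the published material names
  pits only in its pseudo-color legend.
* **Pseudo-color** -- fixed lookup (nuclei blue, matrix gray, pits
  pink, background white; the 600 nm class yellow for normal slides
  and red for tumor slides), with overlap priority
  nucleus > bright600 > pit > matrix so every pixel gets exactly one
  color.  The droplet/pearl semantic split is driven by the slide's
  grade label; no spectral droplet-vs-pearl discriminator is claimed.

# Quantification

`selectWindows()` slides a 200 × 200 px window on a 50 px stride and
applies three quality rules: mean 630 nm intensity within 10--90 % of
the gray range (exposure), tissue centroid inside the central
50 % × 50 % of the window (excludes under-exposed margins and
nucleus/pearl junctions), and bright600 pixels under 5 % of the window
(keratin-pearl exclusion; pearls exist only in tumor tissue, so the
rule is vacuous for normal slides, whose bright600 class holds lipid
droplets).  Among passing windows, five per mosaic are
chosen greedily by descending tissue coverage under a pairwise
non-overlap constraint, ties broken in row-major scan order; with two
mosaics per slide this yields the design count of ten windows per
section.  The exposure bounds, centrality fraction and stride are
config-exposed operationalizations -- the published description of the
window QC is qualitative.

`ncRatio()` is nucleus pixels over cytoplasm pixels (tissue minus
nuclei).  The published analyses alternate between a
"nucleo/plasmic ratio" and a "nuclear area proportion", so a
`mode = "window"` variant divides by the whole window area instead;
`cyto` is the default.  `nucleusAreas()` converts per-instance pixel
counts through the pixel-size calibration (default 0.5 µm/px,
config-supplied -- the published material gives scale bars but not the
pixel pitch, and every µm² threshold passes through this calibration).
`fractionBelow()` computes the atypia fractions below 10/20/30/40 µm²
with the per-nucleus below-20 flag used by the blue/red overlay;
`keratinPearlStats()` counts 600 nm-class instances of at least
100 µm² (an invented, config-exposed floor that suppresses specks).

# Statistics

`tTestGroups()` is the classical pooled-variance two-sided Student's
t-test (Welch correction available but off by default, matching the
published analysis); two zero-variance groups with equal means return
p = 1 by convention.  `rocCurve()` sweeps the unique score values and
computes AUC through the Mann--Whitney identity with midrank tie
handling, so the trapezoidal curve integral equals the U-statistic
exactly.  `gradeComparisonReport()` runs the three pairwise grade
comparisons (plus optionally normal vs pooled tumor); the ROC positive
class is the higher-malignancy grade of each pair, and the summary also
reports the orientation-free max(AUC, 1−AUC).  No multiple-testing
correction is applied across the three pairs, matching the published
analysis; the report says so.

# Reproducibility and problem sizes

All randomness flows from one root seed through named substreams
(`splitSeed(seed, label)`), so changing one stage's draw never shifts
another's.  Reruns with the same config produce byte-identical CSV
outputs.

The validation studies bundled with the package use phantom fields of
600 × 600 px (t-ratio study: 10 fields per grade, ≥ 100 QC windows) and
400 × 400 px (atypia study: 25 fields per tumor grade; the generator's
minimum field), two-tile strips of 400--600 px tiles at 30 % overlap for
the stitching oracle, and a one-slide-per-grade end-to-end run for the
design-count check.  These sizes were chosen to exercise every code
path at full statistical strength while keeping a complete validation
run on a single CPU in the tens of minutes.

# What the phantom does and does not show

The generator emulates: per-band Beer--Lambert contrast of the two
dyes, grade-specific object geometry and rates, vignetting, sensor
noise, frame averaging, and overlapping tile acquisition.  It does
**not** emulate: light scattering, defocus/PSF blur, chromatic
aberration, staining batch variation, touching/overlapping nuclei in
dense sheets (unless `allowContact` is set), mitoses, inflammation, or
the continuum of borderline differentiation.  Passing the recovery
studies therefore demonstrates the *internal correctness* of the
pipeline -- segmentation recovers known geometry, statistics recover
designed contrasts -- not clinical performance on real slides.  In
particular, the designed within-tumor overlap of the NC ratio mirrors
the published observation that the NC ratio barely separates the two
tumor grades, but real-slide AUCs and p-values are external quantities
this package does not claim to reproduce.

# Known limitations

* Lipid droplets are spectrally identical to unstained inter-fiber
  space (both are clear vacuoles), so the droplet mask relies on
  geometric heuristics (enclosure, size, roundness) and has limited
  precision on heavily textured dermis; no staging statistic depends
  on it.
* The random-forest classifier is trained on phantom truth; applying
  it to real stacks requires user annotations (same API).
* Stitching supports linear strips with pairwise chaining; 2-D grid
  bundle adjustment and exposure harmonization are out of scope.
* The pit detector is a geometric proxy (large enclosed tissue holes)
  and is only evaluated qualitatively.
* Vendor formats (CZI, ND2, DICOM-WSI) are not read; stacks enter as
  multi-page TIFF or per-band `band_<wavelength>nm.*` files.
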