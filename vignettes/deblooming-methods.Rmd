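---
title: "De-blooming calcified plaques in simulated coronary CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-blooming calcified plaques in simulated coronary CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Calcified coronary plaques appear larger on CT angiography than they are.
Two deterministic mechanisms drive this *blooming*: the finite spatial
resolution of the reconstruction (the point-spread function smears the
high-attenuation calcium into neighbouring voxels) and beam hardening (a
polychromatic beam produces dark rims and streaks next to dense objects).
The inflated calcium hides the contrast-filled lumen behind it, so readers
systematically overestimate stenosis severity, which depresses the
specificity of CCTA in calcified segments.

`debloomr` provides a desk-scale laboratory for studying this effect and
its correction: a digital vessel phantom with known ground truth, a
forward model that manufactures blooming, an iterative deconvolution that
undoes it where calcium lives, and the quantification and statistics
needed to score the result.

## The phantom

A phantom is a straight vessel along z: contrast-filled lumen (inner
diameter 3.5 or 4.0 mm; attenuation drawn uniformly from 335--365 HU, the
diluted-contrast range at 100 kVp), a 1.0 mm acrylic wall (120 HU) and
background at -50 HU. The plaque is a cylinder of hydroxyapatite-like
attenuation (drawn from 1097--2910 HU) running parallel to the vessel
axis, internally tangent to the inner wall, with diameter

\[ d_\text{plaque} = \frac{\text{stenosis\%}}{100} \times D_\text{lumen}. \]

**Why a full tangent cylinder.** The study this emulates pairs a 3.6 mm
plaque with a 90% stenosis of a 4.0 mm lumen, i.e. the plaque "size"
equals the reduction of the free-lumen diameter. Only a solid protruding
its full diameter into the lumen satisfies that ladder; a half-cylinder
lying flat on the wall would protrude half as much and break both the
plaque-size table and any caliper measurement of the ground truth. The
tangent cylinder also keeps the analytic calcium volume trivially
available, \(\pi (d/2)^2 L\) (default length \(L = 4\) mm, a typical
focal-plaque extent).

Voxels on material boundaries take the volume-weighted mean HU:
rasterization supersamples each in-plane pixel 4x4-fold (the geometry is
z-extruded, so axial overlap is computed exactly). At this factor the
rasterized plaque volume is within 2% of the analytic cylinder; the test
suite verifies convergence with the supersampling factor. The grid default
is 512-matrix spacing at a 12 cm display field of view
(120/512 = 0.234375 mm) with 0.625 mm slices; tests run a 96 x 96 x 24
crop centred on the vessel, which changes nothing physical because the
vessel never approaches the boundary.

## The scanner forward model

The reconstruction is modelled in the image domain:

\[ y = h \ast x \;-\; \beta\,\max\!\big(0,\; g_{w}\ast C - g_{n}\ast C\big) \;+\; \varepsilon \]

* \(h\): separable Gaussian PSF. In-plane FWHM 0.80 mm for the standard
  (STND) kernel and 0.50 mm for the high-definition (HD STND) kernel;
  axial FWHM 0.625 mm (slice-thickness limited). Vendor kernels are
  proprietary, so these are calibration knobs, not measurements.
* dark rim: \(C\) is the truth masked to calcium (>= 800 HU); the
  difference of a wide (0.9 mm) and a narrow (0.3 mm) Gaussian of \(C\),
  rectified and scaled by \(\beta\) (default 0.05), darkens a shell of
  tissue hugging the plaque, mimicking beam hardening. The rim is zeroed
  on calcium itself so the plaque's own attenuation is not reduced before
  blurring.
* \(\varepsilon\): white Gaussian noise, 8 HU (STND) or 15 HU (HD STND),
  seeded. Real CT noise is textured by the reconstruction kernel; white
  noise is a deliberate simplification.

A projection-domain polychromatic simulation with filtered
back-projection would be more faithful but is out of scope; the image-domain
forward model reproduces the two phenomena that matter here --
apparent calcium growth and the sub-luminal dark rim -- at interactive
speed, linearly and shift-invariantly (both properties are tested).

## The de-blooming correction

The correction seeks the image \(x\) whose re-blurred version matches the
observation, i.e. it minimises

\[ \tfrac12 \lVert h \ast x - y \rVert_2^2 \;+\; \tfrac{\lambda}{2} \lVert \nabla x \rVert_2^2 \]

by projected Landweber iteration from \(x_0 = y\):

\[ x_{k+1} = \Big[ x_k + \alpha\, \tilde h \ast (y - h \ast x_k) - \alpha \lambda\, \nabla^{\!\top}\!\nabla x_k \Big]_{\ge \text{HU}_\text{floor}} \]

with \(\tilde h\) the mirrored (adjoint) kernel. Landweber is the
canonical iterative least-squares deconvolution and directly embodies
"minimise the difference between the reconstructed image and the
corrected image convolved with the PSF"; Richardson--Lucy was rejected
because HU values are not Poisson counts (they are signed and the noise
is additive). For a unit-sum PSF the operator norm is 1, so the residual
is provably non-increasing for \(\alpha \le 1\) with \(\lambda = 0\); the
suite asserts this trajectory on every tested run. The small Tikhonov
term (\(\lambda = 0.01\) by default) damps the overshoot/undershoot
ringing classical deconvolution is known for; \(\lambda = 0\) is
supported and used by the oracle tests.

The correction is *masked*: restoration is only wanted where high-density
objects corrupt the image. Voxels >= 600 HU seed a calcium mask, dilated
by twice the in-plane FWHM; \(x - y\) is applied inside the mask with a
cosine taper (0.5 mm) at the boundary, so the output is bit-for-bit the
input elsewhere (tested). The solver itself runs on the mask's bounding
box padded by the kernel support, which makes the iteration cost
independent of the grid size. An empty mask is an explicit no-op, and an
identity PSF returns the input unchanged (the fixed point at zero
residual).

Stopping is dual: `max_iter` (50) or a relative residual change below
`tol` (1e-4); both are recorded in the convergence report together with
the residual trajectory.

**What restoration can and cannot achieve.** A Gaussian PSF annihilates
high spatial frequencies, and Landweber recovers frequency \(\omega\) at
rate \(1 - (1 - |H(\omega)|^2)^k\), so the sharp plaque edge is never
fully recovered at finite \(k\): on the noiseless matched-PSF phantom the
in-mask RMSE drops from ~123 HU to ~75 HU at 50 iterations (bounds
asserted in the suite) rather than to near zero. This is intrinsic to the
method, not a tuning failure.

## Quantification

Lumen segmentation uses the full-width-at-half-maximum convention: a
voxel is lumen when its HU is at least midway between an in-image lumen
reference (vessel core on plaque-free slices) and a background reference,
and below the 600 HU calcium threshold. Because both references come
from the image, measurements are invariant to small global HU shifts and
to the display window; the clinical 1500/300 HU window matters only for
rendering. 600 HU separates contrast (<= ~365 HU) from phantom calcium
(>= 1097 HU) with margin on both sides -- the classic 130 HU scoring
threshold would swallow the contrast-filled lumen entirely.

Diameter stenosis is measured with a *caliper*: per slice, the free-lumen
extent is the longest contiguous lumen run along the diameter through the
plaque centroid, and stenosis is one minus the minimal lesion extent over
the mean reference extent. The area-derived effective diameter
\(2\sqrt{A/\pi}\) is available as `method = "area"`, but for an eccentric
plaque it is not the right instrument: a 50% caliper stenosis removes
only 25% of the area, so the effective diameter reads ~13% -- the caliper
reproduces the construction value (50 +- 3, tested) and mirrors how
stenosis was read in the emulated workflow. Area stenosis proper is the
analogous ratio of segmented lumen areas, validated against the analytic
occluded fraction.

Calcium volume is thresholded voxel counting times the voxel volume; SNR
is the mean lumen HU over the SD of a peripheral background ROI, with the
SD doubling as the noise estimate.

## Statistics

Bland--Altman agreement uses the sample (n-1) SD and 1.96 limits, which
makes the limits exactly symmetric about the bias (so printed limits pin
the printed bias). Diagnostic performance dichotomises both measurement
and truth at the inclusive >= threshold; confidence intervals are exact
Clopper--Pearson from beta quantiles -- chosen because a printed lower
bound of 85.9% for a 100% sensitivity is what the exact interval gives at
n = 24, which Wilson does not. Reduction metrics (RCV, RDS, RAS) are
per-plaque fractional reductions; group summaries are means of per-plaque
reductions, deliberately not reductions of group means (the two differ).
Group comparisons of SNR and noise use a two-sided two-sample t-test (the
emulated analysis does not name its test; this is declared, not derived).

## What the synthetic world does and does not establish

The generator reproduces the *stated* conditions: two lumen diameters,
nine stenoses in 10% steps, the printed HU ranges, grid and slice
geometry, and kernel-dependent resolution/noise pairs. It does not
reproduce: cardiac motion (the pulsating phantom and gating are out of
scope), textured reconstruction noise, polychromatic spectra, curved or
branching vessels, or the vendor's actual PSF and correction algorithm.
Consequently a green test establishes internal consistency of the method
chain -- overestimation appears, correction reduces it, specificity does
not fall -- not numeric equality with scanner measurements. Two measured
divergences are worth naming:

* With the window-independent caliper, the simulated overestimation bias
  is a few percentage points, far below the ~25% a human reader sees at a
  1500/300 window where calcium is visually saturated. The PSF widths are
  kept at their declared defaults rather than inflated to chase that
  number.
* "De-blooming always shrinks measured calcium volume" holds only where
  the PSF's halo outweighs partial-volume dilution of the plaque's own
  boundary voxels: >= 1.2 mm plaques under STND, >= 2.0 mm under the
  near-delta HD kernel. Sub-voxel plaques blur *below* the 600 HU
  threshold, so a faithful restoration *increases* their measured volume
  toward the truth. The corresponding literal acceptance assertion is
  left failing by design, with this analysis.

## Numerical choices

* PSF taps sample the continuous Gaussian at voxel centres and are
  renormalised; support is 4 FWHM per axis. Stored FWHM is measured by a
  log-parabola fit (exact for sampled Gaussians even at one tap per
  FWHM); the half-maximum--crossing measurement is also exposed and is
  accurate wherever sampling is fine relative to the width. Sub-voxel
  requested widths fall back to a minimum-width kernel with a warning.
* Convolution replicates edge values; all solver operators use the same
  boundary rule so the adjoint pairing used by Landweber stays exact on
  interior-supported signals (tested).
* The taper depth is computed by onion-peeling erosion in voxel layers --
  an approximation to the Euclidean distance that is exact to half a
  voxel at the 0.5 mm widths used here.
* Every stochastic draw (HU values, noise) flows from one integer seed
  through a splitter, so a full experiment is reproducible byte-for-byte
  in its CSV outputs.

## Known limitations

Straight vessels only; one plaque per vessel; no blind PSF estimation
(the correction must be told the kernel it is undoing); DICOM import is
minimal (explicit-VR little-endian, single-frame CT) and read-only; the
54-plaque replication preset is an emulation of the physical study's
inventory, whose exact factorisation into diameters, stenoses and repeats
was never published.
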