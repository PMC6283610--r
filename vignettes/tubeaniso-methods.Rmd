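---
title: "Quantifying junctional anisotropy in epithelial tubes: models and methods"
author: "tubeaniso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junctional anisotropy in epithelial tubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubeaniso)
```

# The scientific problem

Tubular epithelia, such as the *Drosophila* tracheal dorsal trunk (DT),
elongate by polarised apical membrane growth. A central observable in
this process is the **anisotropic accumulation of junctional proteins**:
apical determinants such as Crumbs (Crb) can be enriched at cell
junctions running parallel to the tube's long axis (longitudinal cell
junctions, LCJs) relative to junctions running around the circumference
(transverse cell junctions, TCJs), while structural junction components
such as DE-cadherin are distributed uniformly. `tubeaniso` implements
the quantitative image-analysis pipeline for this kind of study:

1. **Junction anisotropy** — classify junctions by orientation, measure
   junctional fluorescence per unit length on intensity projections, and
   pool per-embryo LCJ/TCJ statistics.
2. **Tube unrolling** — map the apical surface of a (possibly bent)
   tube onto a flat circumference-by-length plane and measure apical
   cell areas and orientations there.
3. **FRAP** — normalize photobleaching recovery traces, fit a
   single-exponential recovery, and report mobile fraction and
   half-time.
4. **Morphometrics** — tube length ratios, diameters, and subcellular
   SAR/AFR (subapical region vs apical free region) accumulation.
5. **A ground-truthed synthetic generator** that emulates confocal
   stacks of a labelled tubular epithelium, so every stage above can be
   validated against known truth without microscope data.

Because no real image data ship with the package, all calibration
claims in the test suite are statements about the synthetic generator's
study conditions, detailed below.

# Junction classification and the anisotropy ratio

With the tube's longitudinal axis at 0°, a junction's orientation is
the angle of its end-to-end chord, folded into [0°, 90°] by
$\theta_f = \min(\theta \bmod 180°, 180° - \theta \bmod 180°)$.
Junctions with $\theta_f \le 30°$ are LCJs, those with
$\theta_f \ge 60°$ TCJs, and the band boundaries are inclusive (the
protocol's "±30°" does not exclude its endpoint, and inclusivity
maximizes the assigned fraction). Oblique junctions are reported but
excluded from the ratio; in practice 80–90% of junctions are
assignable, which the synthetic tessellation reproduces
(`fractionAssigned` in the per-embryo table).

The fluorescence of each junction is the **raw integrated density**
over a 5-pixel-wide band along the traced junction:
`bandIntegratedDensity()` samples the projection bilinearly at unit
arclength spacing along the trace and at the 5 unit-spaced
perpendicular offsets (−2…+2), scaled by the arclength step. On a
straight segment over a constant image this equals
value × length × width exactly; against a rasterized-mask oracle it
agrees to better than 2% on smooth images. Per-embryo statistics are
**pooled, never junction-averaged**:

$$\mathrm{density}_L = \frac{\sum_j I_j}{\sum_j \ell_j}
  \quad (j \in \mathrm{LCJ}), \qquad
  R = \frac{\mathrm{density}_L}{\mathrm{density}_T}, \qquad
  D = 100\,\frac{\mathrm{density}_L - \mathrm{density}_T}
               {\mathrm{density}_L}.$$

$D$ is defined relative to the LCJ density: at $R = 1.5$,
$D = 100(1 - 1/R) \approx 33\%$, which reconciles a reported ratio of
1.5 with a reported "around 30% higher" level. Ratios are computed per
embryo and compared across embryos — never pooled across embryos first
— which removes staining-batch effects.

`compareConditions()` is the classical unpaired two-tailed
equal-variance Student t-test with the star convention \*
$p<0.05$, \*\* $p<0.01$, \*\*\* $p<0.001$. (The middle band is stated
ambiguously in some legends; it is interpreted here as
$0.001 < p < 0.01$.)

# The synthetic tubular epithelium

`tubeSpec()` + `tessellateTube()` + `assignIntensities()` +
`renderVolume()` generate a ground-truthed synthetic embryo.

**Tessellation.** Cells are laid out as a brick wall on the unrolled
rectangle $[0, 2\pi r) \times [0, L]$ — `nRings` rows along the axis,
`nAround` cells around the circumference, alternate rows offset by half
a cell — then wrapped onto the cylinder. Bricks rather than a Voronoi
tessellation: junction orientations are controllable, the junction
census has a closed form the tests can verify independently, and
`vertexJitter` (a fraction of cell size, applied to interior vertices
only) restores realism. Because jittered vertices are shared between
neighbouring polygons, the tessellation tiles the surface *exactly*:
the true cell areas always sum to $2\pi r L$ (tested at $10^{-6}$
relative), which makes the tessellation itself the area oracle for the
unrolling stage.

**Intensities.** Each junction draws an intensity density (counts per
µm) from a lognormal with coefficient of variation `intensityCV` and
mean `baseIntensity` for the transverse class, `baseIntensity *
enrichment` for the longitudinal class; oblique junctions interpolate
the mean linearly in folded angle between the 30° and 60° boundaries,
avoiding a discontinuity. Lognormal because fluorescence intensities
are positive and right-skewed; the CV is the single dial. `enrichment`
is the ground-truth anisotropy: 1 emulates a DE-cad-like control, 1.5
the wild-type Crb value.

**Rendering.** Junction polylines are splatted as line sources at 3×
sub-voxel supersampling (removing rasterization bias, so the voxel sum
equals $\sum_j d_j \ell_j$ — the flux oracle), convolved with an
isotropic Gaussian PSF, and corrupted with shot noise (variance =
`shotScale` × signal) plus additive Gaussian read noise. With
anisotropic voxels the PSF is expressed per axis in voxel units.

## Default imaging parameters and why

No instrument parameters come with the study this package models, so
the generator's defaults are chosen once for physical plausibility of
a high-NA confocal and documented here:

* `psfSigma = 0.15` µm (isotropic). A 63×/1.4 NA confocal has a
  lateral FWHM near 0.2–0.3 µm, i.e. σ ≈ 0.1–0.15 µm. A much larger
  placeholder (e.g. σ = 0.3 µm, FWHM 0.7 µm) would make the blur
  comparable to the length of the shortest junctions and bleed
  signal across neighbouring junctions at a level no real 63× confocal
  produces, destroying the very contrast the pipeline measures.
* `voxel = c(0.12, 0.12, 0.125)` µm. Lateral sampling at ≈0.8× σ and
  axial sampling with σ/Δz = 1.2. Axial sampling matters specifically
  because the pipeline max-projects: a maximum over z-samples of a
  barely-sampled Gaussian peak is systematically attenuated by a
  factor that depends on where the junction sits relative to the slice
  grid, which would bias classes differently. The renderer warns when
  the PSF drops below 0.5 voxel on any axis. The 5-pixel measuring
  band is then 0.6 µm wide — it covers the whole blurred junctional
  area (FWHM ≈ 0.35 µm), matching how the band width is meant to be
  used.
* `baseIntensity = 12000` counts/µm with `shotScale = 1`: the peak
  voxel value of a junction line is then ≈150 counts, so treating
  counts as photons gives a peak SNR ≈ 12 — a typical good confocal
  junction image, shot-noise-limited.
* `readSD = NA` defaults to 2% of the ideal peak line amplitude.
* Geometry: radius 6 µm, length 35 µm, 7 rings × 6 cells → cells
  ≈ 6.3 µm around × 5 µm along, LCJs of 5 µm and TCJs of ≈3.1 µm,
  inside the 2.5–9 µm range junctions span in this tissue; 126
  junctions per tube, of which ≈35–40 fall in the measured window
  below — matching the scale of a per-embryo measurement session.

# The end-to-end anisotropy study

`analyzeSyntheticEmbryo()` runs the measurement exactly as an analyst
would on one embryo:

1. Render the stack and **max-project the apical substack** — the
   slices from just above the tube apex down to the depth of the
   deepest measured junction (plus PSF support). Projecting the whole
   upper half instead would fold the tube's steep side walls into the
   projection, where the circumferential signal piles up at the
   silhouette and bleeds into nearby measuring bands.
2. Measure the junctions within ±60° of tube-top azimuth (the
   junctions that can be followed reliably on such a projection),
   classifying by the *projected* chord angle, as a protractor
   measurement on the image does.
3. Trace each junction from vertex to vertex but **stop the measuring
   line short of the tricellular vertices** (by 2σ + half the band
   width, ≈0.6 µm at the defaults). At a vertex three junctions'
   blurred signals overlap into one bright blob that belongs to no
   single junction; including it mixes the classes' intensities and
   attenuates the ratio toward 1. Junctions too short to measure clear
   of both their vertices are skipped, exactly as an analyst skips
   junctions they cannot trace unambiguously.
4. Pool by class (`embryoAnisotropy()`).

`anisotropyStudy()` repeats this over independently seeded embryos.
Under the defaults the estimator is calibrated: across 15-embryo
cohorts the mean ratio is 1.00 ± 0.02 (cohort-to-cohort s.e.) at
enrichment 1 and ≈1.45–1.50 at enrichment 1.5, with the mean percent
difference near its analytic 33%. These are the checks in
`tests/testthat/test-acceptance.R` and the quantities
`scripts/acceptance.R` recomputes.

# Tube unrolling

The unrolling chain reproduces the two-pass straightening macro used
on real stacks:

1. `resampleIsotropic()` — trilinear resampling to cubic voxels (edge
   = smallest input edge), so the projection has no aspect
   distortion. Label volumes use nearest-neighbour sampling instead.
2. `straightenPass(view = "XY")` then `straightenPass(view = "XZ")` —
   two sequential 2D straightenings along the hand-drawn medial axis,
   exactly as the two-step macro operates, rather than a single 3D
   Frenet-frame resampling; this reproduces the operator, including
   its (small) double-interpolation cost. The polyline is smoothed
   with a centripetal Catmull-Rom spline before tangents are taken:
   raw hand-drawn polylines have corner discontinuities that would
   shear the output. Out-of-volume samples are NA (masked), and
   masked pixels are excluded from measurements rather than counted
   as zeros.
3. `unrollTube()` — for each slice along the straightened axis,
   bilinear samples at 1-pixel arc spacing around a circular ring at
   the cell layer become one image row: the vertical axis of the
   unrolled image develops along the tube's longitudinal axis, the
   horizontal axis along the circumference. The width before
   replication is round(perimeter / pixel size). The image is then
   replicated horizontally so cells crossing the azimuthal seam can
   be measured whole; `measureUnrolledCells()` picks, per cell, the
   largest connected component not touching a vertical edge, which
   makes areas and orientations independent of the ring's azimuthal
   origin (tested by rotating the origin arbitrarily).

The ring is a circle (centre + radius): the synthetic tubes have a
circular cross-section and constant diameter — the same assumption the
two-pass macro makes. Validation uses `renderLabelVolume()`: a thin
shell at the cell layer painted with cell ids, pushed through the
identical chain with nearest-neighbour sampling. On a straight
10 × 50 µm cylinder the measured areas sum to $2\pi rL$ within 3%; on
a quarter-torus bend within 5%.

**Cell orientation** comes from the second-moment (inertia) ellipse:
$\varphi$ is the major-axis angle in [0°, 180°), measured from the
horizontal (circumferential) axis of the unrolled plane, so
$\varphi = 90°$ means a longitudinally elongated cell. The study this
package models states the reference frame both as "angle to the A-P
axis" and as "the vertical position (90°) develops along the
longitudinal axis"; the package adopts the image convention (vertical
= longitudinal = 90°) and documents it rather than guessing intent.
Angles ≥180° are reduced by 180° and binned into six 30° intervals
I–VI; near-circular cells (eccentricity < 0.1) are flagged
orientation-indeterminate.

# FRAP

Traces carry `nPre` pre-bleach frames; t = 0 is the *first post-bleach
frame* (the bleach event itself is not a sample). Normalization
divides by the pre-bleach mean only — no reference-ROI double
normalization and no acquisition-bleaching correction, since adding an
unstated reference would change the meaning of the mobile fraction.
The recovery model is the single exponential

$$F(t) = F_\infty - (F_\infty - F_b)\,e^{-kt}, \qquad
  t_{1/2} = \ln 2 / k, \qquad
  M_f = \frac{F_\infty - F_b}{F_{pre} - F_b},$$

fitted to the post-bleach samples by Levenberg–Marquardt least squares
(`minpack.lm`), with starting values $F_b$ = first post-bleach sample,
$F_\infty$ = mean of the last 10% of samples, $k = 4\ln 2/T$. The
floor $F_b$ is a free parameter by default — robust to noise in the
single first post-bleach frame — with `pinFloor = TRUE` available to
pin it. Flat traces return $M_f = 0$ (flagged "flat"); fits with
$M_f > 1$ or non-convergence are flagged, and a non-positive rate is
rejected. On noiseless simulated traces the fit inverts the generator
to $10^{-6}$ relative; on noisy traces (σ = 0.02, 10 s frames,
10 min) the median recovered $M_f$ is within ±0.05 and the median
$t_{1/2}$ within ±10% of truth.

Registration is integer-pixel translation by FFT cross-correlation
against the first frame, matching the stated purpose (correcting xy
embryo movement) at far lower complexity than full rigid registration;
sub-pixel refinement is out of scope. Kymographs stack per-frame
bilinear line profiles (after optional Gaussian denoising) with time on
the horizontal axis; the "no lateral spread" conclusion they support is
a visual judgement the package reproduces as an image, not a statistic.

# Morphometrics and SAR/AFR

Tube length is reported as tube length / embryo length (dimensionless,
robust to magnification); the diameter is the mean of exactly three
line measurements placed by the operator. For subcellular
accumulation on sum projections, SAR is the *mean* intensity in a
6-pixel band centred on the traced cell contour and AFR the mean of
the interior excluding the band (the band's inner edge is not part of
the AFR); means make the SAR/AFR ratio 1 on uniform signal and
comparable across cell sizes, while the `total` (integrated band +
integrated interior) serves absolute cross-genotype comparisons, where
the background-subtracted projection is used
(`backgroundSubtract()`, modal 256-bin histogram estimate). Within-
embryo ratios are never background-subtracted: a uniform offset enters
numerator and denominator alike and its removal is a cross-condition
concern.

# What the generator does and does not emulate

Emulated: orientation-dependent junctional enrichment with lognormal
per-junction variability; PSF blur, shot and read noise; anisotropic
voxels; tube curvature in the acquisition plane; elongation and rigid
drift over time; single-exponential FRAP recovery. Not emulated:
membrane/cytoplasm background structure, spectral crosstalk,
photobleaching during time-lapse acquisition, non-circular or
varying-diameter cross-sections, and curvature out of the acquisition
plane. Passing tests therefore demonstrate correctness of the
*measurement operators* under known geometry and noise — they cannot
certify biological conclusions on real images, where segmentation
quality, background and optical aberrations add error modes the
generator does not model.

# Numerical choices

* Coordinates are 0-based with continuous coordinates at pixel
  centres; angles are in degrees throughout.
* Interpolation is bilinear/trilinear everywhere intensities are
  resampled; nearest-neighbour for label images.
* The band integral uses the midpoint rule (n = round(L/spacing)
  samples at arclengths (i−½)L/n), which is exact on constant images
  and avoids double-counting at polyline corners.
* Gaussian blur kernels are truncated at 4σ and renormalized;
  convolution is separable with zero padding.
* TIFF output stores 32-bit samples scaled into [0, 1] by a recorded
  factor, with voxel size, origin, axis layout and intensity scale in
  a JSON sidecar (`<path>.json`); the installed TIFF writer exposes no
  tag interface. Round trips are exact to 2⁻³² relative quantization.
  A missing sidecar falls back to 1 µm voxels with a warning.
* Problem sizes in the test suite: unit tests use coarse tubes
  (radius 3–4 µm, 0.25–0.4 µm voxels); the study-condition checks use
  the full defaults above with 15-embryo cohorts, and the unrolling
  oracle a 10 × 50 µm cylinder at 0.4 µm voxels. These sizes are the
  package's chosen study conditions; they keep every validation
  statistically meaningful at interactive runtimes.

# Known limitations

* The junction pipeline assumes a straight tube for the projection
  stage (curved tubes go through the unrolling chain instead).
* Translation-only registration cannot correct rotation or scale
  drift.
* The vertex-trim rule removes a PSF-scale margin at junction ends;
  for junctions shorter than twice the trim (≈1.2 µm at defaults) no
  measurement is attempted.
* The SAR/AFR band is a fixed-width geometric band; it does not adapt
  to local junction thickness.
* The unrolling assumes constant tube diameter; diameter variation
  along the axis maps into area distortion of the unrolled plane.
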