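---
title: "Models and methods behind uexm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uexm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uexm)
```

# Scope

Expansion microscopy of microbes (uExM) embeds cells in a swellable
hydrogel that expands roughly 4x in water. Because the bacterial cell wall
is anchored to the gel but resists stretching, the apparent expansion of an
individual cell reports the mechanical state of its wall: intact
gram-positive walls barely expand (~1.2x), partially digested walls expand
intermediately, and fully digested walls expand with the gel (~4x). Two
quantitative consequences follow and this package implements both:

1. **Image quantification.** Cell width, measured on segmented cells,
   becomes a species- and treatment-specific readout. The package provides
   a synthetic micrograph generator with exact ground truth, a
   threshold/distance-watershed segmentation, five-station width
   morphometry, and the population statistics built on widths: the
   expansion ratio with a cluster-bootstrap SEM, width-based species
   classification, Gaussian-mixture fitting, and DNA-halo phenotype
   calling.
2. **A physical model of DNA escape.** When the wall is damaged, the
   chromosome can translocate through wall pores during gel expansion and
   form a DNA cloud ("halo") around the unexpanded cytoplasm. A
   confined-Gaussian-chain model quantifies the entropic barrier to this
   translocation and the critical chemical potential at which escape
   becomes spontaneous.

No public micrographs accompany the original experiments, so every image
based claim in this package is validated against synthetic data with known
ground truth; the polymer model's printed values are reproduced exactly.

# The translocation model

## Free energy

A chromosome of `N` Kuhn segments (Kuhn length $l_K$) is confined in a
sphere of radius $R$ much smaller than its unconfined radius of gyration
$R_g = \sqrt{N/6}\,l_K$. With segment $m$ held at a wall pore, the chain is
split into an escaped coil of $m$ segments and a confined coil of $N-m$
segments. Under ground-state dominance the free energy in units of $k_BT$
is

$$
F(m) \;=\; -\ln\!\left[1 + \frac{R}{R_g}\sqrt{\frac{N}{\pi m}}\right]
\;+\; \pi^2\,\frac{N-m}{N}\left(\frac{R_g}{R}\right)^2 \;+\; m\,\Delta\mu ,
$$

where $\Delta\mu$ is the per-segment chemical potential outside minus
inside the wall; the expanded, low-density gel cavity around a damaged cell
makes $\Delta\mu < 0$. Substituting $R_g$ collapses the confinement
dependence into a single parameter $z_c = \sqrt{6/\pi}\,R/l_K$:

$$
F(m) = -\ln\!\left(1 + \frac{z_c}{\sqrt m}\right)
 + \pi\,\frac{N-m}{z_c^2} + m\,\Delta\mu .
$$

Setting $dF/dm = 0$ and substituting $x = \sqrt m$ gives the cubic
$2c\,x^3 + 2c\,z_c\,x^2 - z_c = 0$ with $c = \pi/z_c^2 - \Delta\mu$. Its
single positive root is the barrier location $m^* = x^2$ — notably
independent of the chain length $N$. Setting $m^* = 1$ yields the critical
potential at which the barrier vanishes,

$$
\Delta\mu_c = \frac{\pi}{z_c^2} - \frac{z_c}{2\,(1+z_c)}
\;\xrightarrow{\,z_c \to \infty\,}\; -\tfrac12\,k_BT .
$$

```{r}
chain <- chain_quantities(chain_params()) # E. coli: 4.7 Mbp, l_K = 100 nm, R = 1 um
unlist(chain[c("n_kuhn", "rg_nm", "confinement_ratio", "volume_fraction")])
barrier(chain, dmu_kT = 0)
critical_potential(chain)
```

With the E. coli defaults this reproduces $N = 15{,}980$,
$R_g \approx 5.2\,\mu m$, $R/R_g \approx 0.19$, a DNA volume fraction of
about 0.1%, $m^* \approx 23$ segments at $\Delta\mu = 0$
($m^*/(R/l_K)^2 \approx 0.23$), and $\Delta\mu_c \approx -0.45\,k_BT$. The
practical reading: a barrier of only a couple of dozen segments, removable
by a potential difference below thermal energy, means DNA escape is a
sensitive reporter of wall pores of roughly Kuhn-length size — far below
the diffraction limit.

Numerical choices: $m$ is treated as continuous; the cubic is solved by
bracketed bisection on $x \in (1, \infty)$ to relative tolerance $10^{-10}$
(cross-checked against `polyroot` in the tests); energies are in $k_BT$
throughout, with no absolute-temperature parameter; integer reporting
rounds half away from zero. For $\Delta\mu \le \Delta\mu_c$ the profile is
downhill from the first segment and `barrier()` reports no barrier; for
$\Delta\mu \ge \pi/z_c^2$ the profile increases without an interior
maximum and the function refuses the input, as translocation can never
complete there. Two source-level ambiguities are resolved numerically: the
radius of gyration is the standard $\sqrt{N/6}\,l_K$ (the alternative
$N^{1/2} l_K$ form is inconsistent with the quoted 5.2 um), and $N$ is
derived from the genome size and helical rise (matching the quoted 15,980)
rather than from the separately quoted contour length, which disagrees in
the fourth digit.

# The synthetic stated world

`render_scene()` and its variants generate the world the image pipeline is
tested against. Cells are straight spherocylinders (width is insensitive to
the slight curvature of real rods, so curvature is not modeled), sampled
per species from truncated normals (4 SD, and width never exceeding
length), placed by rejection sampling (uniform position inset by half the
cell length, uniform orientation on $[0, \pi)$, minimum centroid
separation, 10,000 attempts per cell, and a 30% frame-area feasibility
bound). Rendering is constant interior intensity, convolution with an
isotropic Gaussian PSF, scaled-Poisson shot noise and additive Gaussian
read noise. A single seed drives everything through deterministic per-cell
substreams, so scenes are bit-reproducible.

Defaults, chosen once as typical confocal values and not revisited:
pixel size 0.1 um/px; PSF sigma 0.1 um (~diffraction-limited visible-light
imaging); background 0.02 of cell amplitude; shot scale 200
photons/intensity unit (SNR ~14 at full signal); read noise 0.01. Cell
geometry defaults in tests follow the measured biology: pre-expansion
widths near 0.8 um (SD 0.05), lengths near 3 um, expansion factors spanning
1.1-4.0, gel factor 4.

The expansion pair (`render_expansion_pair()`) reuses the same sampled
cells: positions scale with the gel factor, cell dimensions with the
species' own expansion factor, and the post frame grows by the gel factor
at constant pixel size (mirroring the convention of rescaling scale bars
rather than resampling images). The halo scene renders every cell's
cytoplasm at its unexpanded size and gives each cell, independently with
the configured probability, a concentric DNA cloud of width
`halo_factor * width` (default 4). The radial DNA profile is not
constrained by any published measurement; an edge-bright annulus
(amplitude 1 on $[0.5, 1] \times r_{out}$, Gaussian shoulders of
$\sigma = 0.05\,r_{out}$, core floor 0.35, overall amplitude half the
cytoplasm's) was chosen to reproduce the rim-peaked intensity profiles the
phenotype shows, and is configurable.

What the generator does **not** emulate: 3D structure (scenes are already
"projected"), curved or dividing cells, crossing cells, autofluorescent
tissue background, camera offset, or gel distortion. A green test therefore
establishes that the pipeline recovers truth under idealized rod geometry
and two-component noise — not that it would survive dense planarian tissue.

# Segmentation

The pipeline is deliberately parameter-light and deterministic: Gaussian
smoothing (1 px) -> global threshold -> exact Euclidean distance transform
of the foreground -> watershed flooding seeded at h-maxima-suppressed
regional maxima of the distance map -> area and border filtering -> dense
relabeling. Foreground is strictly-greater-than the threshold; components
and basins use 8-connectivity; watershed ties break by insertion order,
which is raster order, so results are reproducible to the bit.

Two defaults were fixed by measurement rather than convention:

* **Threshold.** The default is `halfmax`: Otsu's split first, then the
  threshold is placed midway between the *modes* of the two classes — the
  half-maximum of the edge profile. Plain Otsu is provided and tested, but
  on matched pre/post-expansion pairs its threshold drifts low on the
  pre-expansion side, where cells are only ~6 PSF widths across and blurred
  edge-ramp pixels dominate the foreground histogram. That widens small
  cells relative to large ones and biased the recovered expansion ratio by
  about -4%; the half-maximum placement removes the size dependence
  (residual ratio error ~1%). Class modes are used rather than means or
  medians because the ramp pixels drag those below the interior plateau.
* **Marker suppression depth.** The distance-transform ridge of a
  digitized rod oscillates by up to ~0.5 px, so a relative h (2% of the
  range, ~0.1 px here) fragments every cell into many markers. The default
  is `max(1 px, 2% of range)`: the 1 px floor merges pixelation ridges
  while genuine waists between touching cells — several px deep — survive
  and are split.

# Morphometry

The long axis is the principal eigenvector of the pixel-coordinate
covariance (cells are straight in this artifact, so PCA is preferred to
skeletonization); length is the extent of pixel projections on it plus one
pixel. Width is measured at five stations placed at centered fractions
10%, 30%, 50%, 70%, 90% of the axis — "evenly spaced" with no stations at
the poles, where chords degenerate to zero. Each station's width is the
chord of the binary mask perpendicular to the axis: the count of bilinear
samples above 0.5 along the chord line at 0.25 px steps, times the pixel
size. Counting along the whole line (rather than marching to the first
sub-0.5 sample) makes the chord insensitive to the dithered edges of a
noisy threshold mask. Stations falling in a mask gap are interpolated from
neighboring stations and flagged. The aspect ratio is the ratio of
projected extents along the two principal axes, which stays ~1 for
isotropic shapes (the mean five-station chord of a disk underestimates its
diameter, so a chord-based aspect ratio would read ~1.3 for a circle).

The five-station statistic itself slightly underestimates the width of
short cells (outer stations can fall on the hemispherical caps), but the
effect is proportional for geometrically similar cells and cancels in the
expansion ratio.

# Population statistics

* **Expansion ratio** = mean post width / mean pre width. The SEM is a
  cluster bootstrap (default 1,000 resamples) over *images*, not cells,
  respecting within-image correlation; with a single image per arm it falls
  back to resampling cells, with a warning.
* **Classification** assigns each width to the reference normal maximizing
  likelihood x prior (equal priors when unset); posterior ties break
  toward the smaller mean, deterministically. Reference SDs have a floor of
  0.05 um (half a pixel) so quantized or degenerate controls cannot produce
  zero-variance likelihoods. When single-species controls are unavailable,
  `fit_mixture()` fits a 1D Gaussian mixture by EM (quantile-based
  initialization, deterministic given the seed) and flags component pairs
  whose 2 SD intervals overlap as unresolved.
* **Halo calling** measures, per segmented cell, the width of the DNA-mask
  component overlapping it (Otsu threshold inside a window of the cell's
  bounding box dilated by five cell widths; enclosed holes filled so the
  annular cloud is measured by its outer envelope) with the same
  five-station procedure, and calls the cell expanded when the
  DNA/cytoplasm width ratio reaches the cutoff — default 2.0, midway
  between the colocalized ratio ~1 and the full halo ~4. Fractions are
  averaged over replicates with the SEM over replicates.

# Known limitations

* The original experiments' segmentation (an external morphological
  segmentation plugin with undisclosed parameters) cannot be reproduced;
  this pipeline is a functional replacement validated on synthetic truth,
  and equivalence to the original is not claimed.
* The anchoring step of translocation (its barrier depends on an unknown
  anchoring energy) is out of scope; the model covers the post-anchoring
  entropic barrier only, and says nothing about kinetics.
* Width measurement is mask-based; no subpixel intensity fitting is
  attempted, so per-cell widths carry ~half-pixel quantization noise.
* Overlapping or crossing cells are not separated; the generator's minimum
  separation keeps the stated world away from that regime.
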