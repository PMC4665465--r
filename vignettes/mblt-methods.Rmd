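---
title: "Multi-view bioluminescence tomography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view bioluminescence tomography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblt)
```

## The problem

Bioluminescence imaging records the light that luciferase-expressing cells
emit after substrate administration. A single planar image is a poor
quantitative readout: scattering and absorption in the intervening tissue
attenuate and blur the signal, and the recorded intensity can vary by an
order of magnitude with the viewing direction alone. Tomographic imaging
addresses this by acquiring calibrated surface-radiance images from many
angles around the subject and reconstructing the internal source
distribution volumetrically.

`mblt` implements both halves of that workflow for a rotationally acquired
multi-camera geometry: a forward simulator producing calibrated multi-view
acquisitions of point-like sources inside a homogeneous turbid cylinder (the
validation phantom configuration: a 30 mm diameter cylinder of 1 %
Intralipid / 1 % agarose gel, a 1 mm fiber-tip source at 560 nm, 20 views at
18° steps), and a three-step volumetric reconstruction. Because no public
dataset of such acquisitions exists, the simulator is a first-class,
fully-tested component: it defines the study conditions against which the
reconstruction is validated.

## Photon transport model

Light that scatters many times is modeled by the steady-state diffusion
approximation. A homogeneous medium is described by its absorption
coefficient $\mu_a$ (1/mm), reduced scattering coefficient $\mu_s'$ (1/mm)
and refractive index $n$, with the derived quantities

$$D = \frac{1}{3(\mu_a + \mu_s')}, \qquad
  \mu_{\mathrm{eff}} = \sqrt{\mu_a / D}.$$

The relation for $D$ is the standard diffusion-theory one. A point source of
steady-state power $S$ (photons/s) produces the infinite-medium fluence

$$\phi(r) = \frac{S\, e^{-\mu_{\mathrm{eff}} r}}{4 \pi D r},$$

which satisfies $D\nabla^2\phi - \mu_a \phi = 0$ away from the source (a
finite-difference check of this identity is part of the test suite). At the
phantom boundary, the refractive-index mismatch reflects part of the diffuse
field back inside. We use the partial-current (effective-reflection) model:
the outward Lambertian radiance at a surface point with internal fluence
$\phi$ is

$$L = \frac{(1 - R_{\mathrm{eff}})\, \phi}{4\pi (1 + R_{\mathrm{eff}})},$$

with $R_{\mathrm{eff}}$ obtained by numeric quadrature of the unpolarized
Fresnel reflectance over the diffuse angular distribution. For $n = 1$,
$R_{\mathrm{eff}} = 0$; for $n = 1.4$ the quadrature reproduces the
tabulated value 0.493.

Default Intralipid 1 % properties at 560 nm are $\mu_s' = 1.0$/mm,
$\mu_a = 0.002$/mm, $n = 1.34$; they are configuration values, not
constants, and a small registry also ships `air` and a generic soft-tissue
entry. A transparent medium bypasses diffusion entirely and is rendered by
direct inverse-square projection — this is how the bare-fiber ("in air")
control experiments are simulated.

### Validity domain

The infinite-medium Green's function ignores boundary leakage. Compared
against a Monte-Carlo photon-transport oracle (isotropic-scattering random
walk with Fresnel boundary interactions, included in the test suite), the
simulated angular capture profile agrees to within about 10 % over the
views within ±54° of the source azimuth — which carry roughly two thirds of
all captured light — but overestimates the deeply shadowed far side, where
photons that in reality leak out through the nearer boundary are still
credited to the long path. The phantom-level observables (proximal
enhancement relative to air, near/far asymmetry approaching an order of
magnitude) are insensitive to this. Reconstruction is unaffected in its
accuracy contract because simulator and reconstructor share the same
forward model; what the passing tests demonstrate about *real* data is
correspondingly limited to the regime where the diffusion approximation
holds (source depths of several transport mean free paths, homogeneous
media).

## The instrument model

Four camera heads 90° apart rotate through five 18° stops, so the view set
covers all 20 multiples of 18° exactly once; by reciprocity the
implementation rotates the cameras about a fixed scene, which serves both
the camera-rotation and the phantom-rotation descriptions with one code
path. Each head is a thin-lens pinhole camera (25 mm focal length, f/0.95,
512 × 512 pixels of 24 µm) focused on the rotation axis. The default
standoff of 116.5 mm follows from requiring a 30 mm object to span about
two thirds of the field of view with this lens and detector. A resolved
Lambertian surface patch of radiance $L$ deposits
$L \cdot A_{\mathrm{pix}} A_{\mathrm{lens}} / d_i^2 \cdot \cos^4\alpha$ on
a pixel ($d_i$ = image distance, $\alpha$ = field angle); rendering is
pixel-driven (each pixel's ray is cast to the analytic cylinder surface),
which avoids tessellation holes, while the triangle-driven
`surface_pixel_map()` provides the patch-to-pixel geometry with the
$\mathrm{area} \times \cos\theta$ obliqueness weighting for analysis.

The CCD chain applies, in physical order: Poisson shot noise on signal plus
dark current (0.1 e⁻/pixel/s at −50 °C), per-pixel full-well clipping
(350,000 e⁻), on-chip binning (electron sum; one readout per bin), Gaussian
read noise (5 e⁻ RMS), and 16-bit digitization with a bias offset. Binned
readout digitizes summed wells, so the ADC gain scales with $b^2$ — without
that, any bright binned exposure would saturate the digitizer. Absolute
calibration follows the flat-field procedure: imaging a uniform source of
known radiance (3.0 × 10⁻⁷ W/cm²/sr) through the same chain yields a
per-pixel gain map that converts counts/s directly into radiance,
correcting vignetting, pixel response non-uniformity, and the transmission
of the whole optical system in one step. Dead pixels (zero flat signal) are
flagged and excluded. All internal radiance is photons/s/mm²/sr;
conversions to W/cm²/sr use the photon energy $hc/\lambda$.

## Reconstruction

The reconstruction consists of three steps.

**Step 1 — backprojection and source localization.** Calibrated views are
converted to detected photon rates, divided by the boundary-exitance factor
(removing the internal-reflection loss so the transmitted intensity is
processed), and backprojected into the voxel grid. Two forms are provided.
The smear form (`backproject_initial()`) compensates attenuation along each
sight line with the inverse Green's function
$e^{+\mu_{\mathrm{eff}} d}\, 4\pi D d$ and combines views by their
geometric mean: each view's backprojected value is a per-view hypothesis of
the source power at that voxel, and the geometric mean is largest where all
views agree. (A purely additive smear with a depth-growing weight puts its
maximum on the phantom wall — the weight grows monotonically along every
ray — which is why consistency across views, not accumulation alone, has to
carry the localization.) The pipeline's localization then goes further:
point-source candidates are extracted greedily from the
Green's-function-normalized correlation of the backprojected surface data —
for a single source the normalized correlation is maximal exactly at the
true voxel, by Cauchy–Schwarz — and all candidate positions are refined
jointly by Nelder–Mead nonlinear least squares against the surface data,
with amplitudes profiled out linearly and a soft barrier keeping positions
inside the phantom. An explicit source model is used because the surface
data alone cannot distinguish a deep point source from an equivalent
shallower shell: an unconstrained voxel inversion is degenerate in depth,
and the instrument's stated regime is point-like lesions, for which
nonlinear parameter fitting is the appropriate estimator. Model order grows
while the weighted relative residual exceeds 4 % and each added component
improves it by at least 25 %; these thresholds were fixed at design time.
The same rule makes a deep symmetric pair — whose surface signature is
within a fraction of a percent of a single stronger source — collapse to
one component, which is the honest answer the data support (see the
degeneracy demo below). In air, candidates are initialized by intersecting
the per-view image-centroid rays and refined against the rendered pixel
model.

**Step 2 — initial fluence.** The source estimate is convolved with the
diffusion Green's function on the grid (zero-padded FFT convolution; the
self-distance is regularized at half a voxel) and rescaled once so that its
re-projection onto the detectors matches the measured per-view totals — the
measured-over-estimated intensity ratio applied as a global
data-consistency weight.

**Step 3 — EM deblurring.** The fluence field is deblurred by the
multiplicative Richardson–Lucy / EM update

$$\phi^{n+1} = \phi^{n}\,\Big[\big(d / (\phi^{n} \otimes \varrho)\big)
  \otimes \hat\varrho\Big],$$

with $\varrho$ an isotropic Gaussian kernel (default $\sigma$ = 1.5 mm ≈ 3
voxels, truncated at 3σ, unit sum) and $\hat\varrho$ its mirror (identical,
by symmetry). Ratios at zero-denominator voxels are defined as 0; the
update preserves non-negativity and, for unit-sum kernels and
interior-supported data, conserves total intensity exactly (the
zero-padded separable convolution is self-adjoint). Inside `reconstruct()`
the update runs on the phantom-interior domain with the kernel column-sum
(sensitivity) normalization — the standard correction at a finite domain
boundary, without which the deconvolution inflates the ratio near edges
and piles mass at the grid corners. Iteration stops at a relative-change
tolerance of 10⁻⁴ or 200 iterations. Deblurring operates in the volume
domain (the initial fluence already encodes data consistency); per-view
re-projection per iteration is noted as the alternative but not
implemented.

Finally, the deblurred map is normalized to the fitted model's total power,
whose re-projection through the exact forward model matches the measured
views. Re-projecting the RL-broadened volume instead would bias totals by a
few percent, because a spatially spread source has a slightly different
escape geometry than the point it represents. The per-iteration log records
total intensity, relative change, the deconvolution residual, and —
optionally, for diagnostic comparisons such as the half-views check — the
relative residual between the measured surface data and the re-projection
of the current iterate.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `mu_s_prime` | 1.0 | 1/mm | Intralipid 1 % reduced scattering at 560 nm |
| `mu_a` | 0.002 | 1/mm | Intralipid 1 % absorption at 560 nm |
| `refractive_index` | 1.34 | — | gel/air boundary mismatch |
| source power | 1.4 × 10¹⁰ | photons/s | fiber-tip brightness; matches the reconstructed-total scale reported for the physical phantom |
| exposure | 60 | s | per view; 30–300 s supported per session |
| `binning` | 4 | — | on-chip binning of the 512² detector |
| gantry radius | 116.5 | mm | 30 mm phantom ≈ 2/3 of the field of view |
| `sigma_mm` | 1.5 | mm | EM deblurring kernel width (≈ 3 voxels) |
| `max_iter`, `tol` | 200, 10⁻⁴ | — | EM stopping rule |
| `fit_rel_tol`, `fit_improve` | 0.04, 0.75 | — | model-order rule of the localization step |
| grid | 64³ × 0.5 mm | — | reconstruction volume, cropped to the phantom footprint |

The 64³ grid at 0.5 mm voxels covers |z| ≤ 16 mm of the 40 mm phantom;
sources are therefore expected within that axial window (the property tests
draw them at |z| ≤ 10 mm). These problem sizes — 128² binned detector
frames, 20 views, 64³ grids — keep a full simulate-and-reconstruct cycle at
the scale of seconds to a few tens of seconds, which is what makes the
property-based suite (dozens of end-to-end reconstructions) practical.

## What the generator does and does not emulate

The simulator reproduces: the multi-view rotational geometry with per-head
radiometric calibration, absolute-unit imaging of diffuse surface radiance,
the CCD noise chain, the scattering-induced proximal enhancement relative
to air, the far-side shadowing, and exposure-invariant calibrated output.
It does not emulate: heterogeneous or wavelength-dependent optical
properties, luciferin kinetics beyond an optional global source-power
curve, autofluorescence or ambient background, animal surfaces (the mesh is
an analytic cylinder; photograph-based surface reconstruction is out of
scope), partial-volume source extent, or camera distortions beyond cos⁴
vignetting. Tests passing against this generator therefore validate the
reconstruction machinery under the diffusion model's own assumptions; they
do not certify performance on heterogeneous living tissue.

## Numerical choices and degenerate inputs

* World/voxel convention: right-handed, mm, gantry axis = +z, angle 0° on
  +x; voxel centers at `origin + (index − 0.5) · h` (1-based indices).
  Anatomical labels map transverse → z, coronal → y, sagittal → x.
* The Green's-function FFT kernel caps the self-distance at h/2; kernels
  are cached per grid/medium.
* Peak finding uses the 26-neighborhood, greedy suppression strongest-first
  with lexicographic tie-break, and 3-point parabolic sub-voxel refinement
  (clamped to ±half a voxel); raw-voxel mode is available.
* The RL ratio convention 0/0 → 0; any non-finite ratio is dropped.
* All-zero or pure-noise acquisitions reconstruct to a flagged (`low_snr`)
  result rather than an exception; the flag compares each view's peak
  excursion to its robust spread.
* Fixture generation is bit-reproducible from config + seed; the CCD noise
  chain and per-head pixel response fields use isolated RNG streams so user
  code's RNG state is untouched.

## Known limitations

* Homogeneous media only; the diffusion kernel is the infinite-medium one
  with boundary effects handled at the exitance step (see *Validity
  domain*).
* The localization step is designed for a small number of compact sources
  (the model-order cap defaults to 3); extended or highly structured source
  distributions are outside its design envelope, and the deblurred volume
  inherits the fitted model's sparsity.
* Depth degeneracy is intrinsic to surface-fluence data: configurations
  exist (deep pair vs. single stronger source) that no algorithm can
  separate from these measurements. `degenerate_pair_demo()` constructs
  one — surface data differing by well under 1 % of peak while the true
  source maps are disjoint — and the reconstruction deliberately reports
  the single-source explanation in that case.
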