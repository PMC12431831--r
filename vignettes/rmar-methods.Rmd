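---
title: "Regional model-based metal artifact reduction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional model-based metal artifact reduction: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmarct)
```

## The problem

Virtual monochromatic images (VMIs) from dual-energy CT are most valuable
clinically at low energies (around 40–70 keV), where iodine contrast and
soft-tissue differentiation are strongest — and that is exactly where metal
implants ruin them. Beam hardening and photon starvation around titanium
rods, pedicle screws or hip prostheses produce streaks and shading that grow
steeply as the reconstruction energy drops. High-energy VMIs (≥100 keV) are
comparatively clean but diagnostically flat.

`rmarct` implements a regional, image-domain correction that transfers the
cleanliness of the best available high-energy VMI into the low-energy ones.
It never touches projection data from the scanner; everything happens on
reconstructed slices, which makes the method vendor-agnostic.

## The spectral model

Every VMI is a linear combination of two material basis images (MBIs),
water `f_w` and cortical bone `f_b` (g/cm³):

$$ f_{vmi}(E) \;=\; \frac{1000}{\rho_w}\!\left[
     \frac{m_w(E)}{m_w(E)}\,f_w + \frac{m_b(E)}{m_w(E)}\,f_b \right] - 1000 $$

with $m(E)$ mass attenuation coefficients (cm²/g) and $\rho_w$ the water
density. Two VMIs at distinct energies determine $(f_w, f_b)$ pixelwise
through an exact 2×2 solve (`decompose_mbi()`); synthesis at any energy is
the forward evaluation (`synthesize_vmi()`). Because the water coefficient
ratio is identically 1, all energy dependence of a slice — artifacts
included — travels through the bone basis term. A pure-water pixel gives
exactly 0 HU at every energy, and an empty pixel −1000 HU; both are enforced
by tests. The prefactor is $1000/\rho_w$: the alternative reading
$1000\rho_w$ is dimensionally inconsistent with the Hounsfield definition
and fails the pure-water identity.

Mass attenuation coefficients for water, cortical bone and titanium are
shipped as a plain-text table over 15–200 keV at standard reference grid
energies, interpolated log-log (`atten_table()`, `mass_atten()`). Log-log
interpolation tracks the near-power-law photoelectric regime and is
monotone between samples; users may substitute their own table in the same
three-column format.

## The correction procedure

Given a VMI series (default decomposition pair 70/140 keV, the extremes of
the usual clinical set):

1. **Decompose** the pair into `f_w`, `f_b`.
2. **Score artifacts per energy.** For each selected energy (default 70,
   80, 100, 120, 140 keV) a coarse preliminary MAR is run: threshold
   segmentation of metal (default 2500 HU — titanium in VMIs sits far above
   3000 HU, bone below 2000 HU), forward projection, linear interpolation
   across the metal shadow per angle, filtered back projection, metal pixel
   re-insertion. The *artifact image* is the input minus this correction.
   Each artifact image is scored by total variation
   $C = \sum \sqrt{\Delta_x^2 + \Delta_y^2}$ (forward differences, last
   row/column omitted, metal excluded) and the curve is normalized by its
   maximum. The argmin is the optimal energy, the argmax the worst; ties
   resolve to the higher and lower energy respectively, because artifact
   burden falls with energy in the underlying physics.
3. **Build masks.** The body support is everything above −500 HU on the
   optimal VMI, hole-filled, so that air never dominates row statistics.
   Sorting-and-thresholding segmentation (STS) flags, per image row, the
   pixels outside median ± 10 HU of the in-support row values; rows with
   fewer than 3 support pixels are skipped. STS runs twice — on the worst
   energy's artifact image with a 4-pixel erosion element (STS1, the
   obvious artifact core) and on the optimal energy's artifact image with a
   1-pixel element (STS2, a sharper artifact-free complement) — each after
   a 2-pixel dilation. The artifact mask `f_M1` is their union clipped to
   the support and stripped of metal; `f_M0` is the complement within the
   support, off metal.
4. **Fit the regional model.** On `f_M0` pixels with optimal-VMI CT number
   ≤ 150 HU (bone excluded from fitting only), ordinary least squares fits
   `basis = a0 + a1·HU + a2·HU²` separately for water and bone. The design
   is centred and scaled before solving; rank-deficient designs (constant
   CT numbers) and fits on fewer than 100 pixels are refused. Evaluation
   clamps to the fitted HU range — a quadratic extrapolated into a
   −800 HU streak would otherwise invent tissue.
5. **Correct and resynthesize.** `f_M1` pixels of each basis are replaced
   by the model evaluated at the optimal VMI's CT numbers; everything else
   keeps its original value. Corrected VMIs at the output energies copy
   the input outside `f_M1` (metal pixels included) and take the
   synthesis from the improved bases inside it, so the correction is
   *exactly* local: a pixel outside the artifact mask is bit-identical to
   the input.

A series in which no metal is found is returned unchanged with a flag —
implant-free studies are valid inputs, not errors.

### Numerical choices

* The projector is a rotation-based parallel-beam Radon transform with
  bilinear sampling and one-pixel ray steps; reconstruction is ramp-filtered
  (Ram-Lak kernel) back projection with an optional Hann apodization, the
  standard trade of ripple against resolution. The projector reproduces the
  analytic chord-length integral of a homogeneous disc to well under 0.5%
  RMS, and FBP∘Radon of a water disc is accurate to ~3 HU in the interior.
* Preliminary MAR reconstructs the sinogram *modification* rather than the
  full interpolated sinogram: since FBP is linear, `image − FBP(original −
  interpolated)` is analytically identical but cancels the forward/inverse
  roundtrip error exactly outside the metal shadow, keeping the artifact
  image clean where nothing was changed. Inputs are capped at 3071 HU
  before projection — scanner exports are 12-bit-clipped anyway, and the
  cap keeps filter side lobes of synthetic, unclipped metal values from
  polluting the artifact image.
* The 2×2 decomposition refuses energy pairs whose coefficient determinant
  falls below 1e−8 relative to the matrix scale.
* `hu_domain` clamping, the −500 HU support threshold, the 150 HU bone
  exclusion and the 2500 HU metal threshold are all configurable through
  `rmar_config()`.

## The simulator

No public phantom scans exist for this problem, so the package carries its
own measurement model (`synth_phantom`/`simulate_series()`), built around a
digital version of a 200 mm solid-water cylinder holding two 10 mm titanium
rods. Solid water is modelled at 1.015 g/cm³; the slight excess over water
is what makes decomposed bone bases of real solid-water phantoms come out
negative, a sign behaviour the simulator must (and does) reproduce.
Ground truth is the same phantom with the rods replaced by solid water,
synthesized exactly through the spectral model — the identical code path
the pipeline uses.

The physics pathway per detector layer: polychromatic transmission
$I = \sum_E w(E)\,e^{-\sum_m m_m(E)\rho_m t_m}$ on a 1 keV grid, optional
Poisson counting noise at a configurable photon budget (default 2×10⁵ per
bin), a 0.1-photon floor before the log so starved rays produce severe but
bounded streaks, water beam-hardening linearization (the measured
log-signal is mapped through the inverted pure-water layer response, as
scanner calibrations do), Hann-apodized FBP, and conversion to HU at the
layer's mean energy. The two layer images are then treated as
pseudo-monochromatic and decomposed; the VMI series synthesized from those
bases inherits beam hardening and starvation streaks whose amplitude falls
with energy — the qualitative behaviour the correction relies on.

The detection spectra are a deliberately stylized two-layer split of a
filtered bremsstrahlung shape (`spectrum_model()`): the split is sharp
enough that the layer mean energies land near 55 and 105 keV. A physical
dual-layer detector at 140 kV separates its layers less cleanly; the wide
split is chosen so that the 70–140 keV VMI range interpolates between the
layer energies rather than extrapolating far beyond both, which keeps the
artifact-versus-energy trend monotone over the clinical range instead of
re-amplifying noise at 140 keV. This is a simulator design choice, stated
here openly: it emulates the *phenomenology* the method addresses
(energy-dependent metal artifacts with clean high-energy anchors), not any
vendor's detector response.

What the simulator does **not** model: scatter, detector cross-talk,
helical/cone geometry, anatomical backgrounds, vendor iterative
reconstruction. Passing tests on it therefore demonstrate the mechanics
and the physics-level behaviour of the correction, not clinical
performance on patient data.

### Study conditions used by tests

Default test phantom 256×256 over a 350 mm field of view (about half the
linear sampling of a 512 scanner matrix, for test-suite speed; a helper
builds any size), 180 projection angles, photon budget 2×10⁵. The
randomized-layout study rotates the rod pair uniformly, draws its
half-separation from 30–45 mm (around the reference 40 mm) and offsets the
midpoint by up to 12 mm — enough variety to move every mask and model off
any privileged orientation while keeping the inter-rod streak zone, the
structure the evaluation measures, present in all variants. Evaluation
ROIs are placed the way a reader places them — at the strongest
mean-deviation spots of the *uncorrected* low-energy slice relative to
ground truth (`artifact_rois()`), so the correction is judged on ground
the selection never saw. Smaller shared fixtures (160 px) back the unit
tests; 64–128 px cases cover geometry and I/O.

## Known limitations

* The method cannot improve the optimal VMI itself; if every energy is
  badly starved (large prostheses), the model is fitted on corrupt anchors
  and inherits their error. The pipeline accepts an externally
  pre-corrected series as input for exactly that case.
* One global quadratic per basis: no spatial adaptivity. Heterogeneous
  anatomy inside the artifact mask is mapped through a relation fitted
  mostly on other tissue.
* The fit regresses basis density on a single VMI's CT numbers even though
  the bases came from two energies; where the HU→basis relation is not a
  function (distinct tissues sharing HU), the model averages them.
* Slices are processed independently; no through-plane consistency.
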