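---
title: "Simulation methods: transcranial focused ultrasound on a synthetic skull phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`skullwave` simulates the pressure field of a low-frequency (220 kHz)
hemispherical phased array sonicating a brain target through the skull, the
setting of microbubble-enhanced nonthermal ablation.  The pipeline runs
from a pseudo-CT volume in Hounsfield units to beam metrics: material
mapping via a porosity model, Rayleigh-integral source modelling with a
Huygens surface reduction, linear/nonlinear acoustic and viscoelastic
pseudospectral wave solvers, aberration-correction schemes, iso-dB beam
volumes, and passive cavitation detector (PCD) sensitivity maps.

Because clinical/animal CT data are not redistributable, the package ships
a *synthetic* skull-phantom generator; every phantom object and file is
synthetic by construction.  Water-only device physics (focal volumes,
steering, the Huygens reduction, the discretization error study) is at full
scale and quantitative.  Skull-mediated effects are exercised on the
phantom and validated as *properties* (orderings, equivalences, monotone
responses), not as reproductions of animal-specific numbers.

# Governing equations

The acoustic solver advances the coupled first-order system

$$\partial_t \mathbf u = -\tfrac{1}{\rho_0}\nabla p, \qquad
  \partial_t \rho = -(2\rho + \rho_0)\,\nabla\!\cdot\!\mathbf u, \qquad
  p = c_0^2\Big(\rho + \tfrac{B}{2A}\tfrac{\rho^2}{\rho_0} + L\rho\Big),$$

with $\rho$ the acoustic density perturbation, $B/A$ the nonlinearity
parameter and $L$ a power-law absorption/dispersion operator.  In linear
mode the $(2\rho)$ and $B/A$ terms are dropped.  Density heterogeneity is
handled by the $\rho_0$ fields in the momentum and mass balances, which
together reproduce the heterogeneous second-order wave equation without an
explicit displacement term.

Spatial derivatives are spectral on staggered grids (half-voxel shifts
applied in the wavenumber domain) with the temporal k-space correction
$\kappa = \mathrm{sinc}(c_{\mathrm{ref}} k \,\Delta t/2)$,
$c_{\mathrm{ref}}$ the map maximum.  This makes homogeneous propagation
exact at any stable CFL number; the default CFL is 0.3.  Boundaries are
split-field perfectly matched layers (10 voxels, quartic profile, 2 Np per
voxel at peak).

The viscoelastic solver advances the Kelvin-Voigt velocity-stress system

$$\partial_t \sigma_{ij} = \lambda\delta_{ij}\,\partial_k v_k
 + \mu(\partial_j v_i + \partial_i v_j)
 + \chi\delta_{ij}\,\partial_t\partial_k v_k
 + \eta\,\partial_t(\partial_j v_i + \partial_i v_j), \qquad
 \rho_0\,\partial_t v_i = \partial_j \sigma_{ij},$$

as a plain pseudospectral leapfrog (no k-space correction; CFL default
0.2) with multi-axis split-field PML.  Fluid voxels are carried with
$\mu = 0$, so fluid-solid coupling is implicit in the voxel maps.  The
viscous terms use the time difference of the strain-rate gradients, a
first-order-consistent approximation.  The scalar "pressure" recorded in
solids is the mean normal stress $-(\sigma_{xx}+\sigma_{yy}+\sigma_{zz})/3$
(the choice is a convention; nothing in the published metrics depends on
the solid-voxel values).

# Material mapping

CT Hounsfield units map to skull porosity $\psi = 1 - H/1000$ (clamped to
$[0,1]$), then to compressional properties by linear mixing between water
and dense cortical bone for speed and density, and a square-root porosity
law for absorption:

* $c_{\mathrm{skull}} = 1480\,\psi + 3100\,(1-\psi)$ m/s
* $\rho_{\mathrm{skull}} = 1000\,\psi + 2200\,(1-\psi)$ kg/m³
* $\alpha_{\mathrm{skull}} = 0.64 + (25.46-0.64)\sqrt{\psi}$ dB MHz⁻¹ cm⁻¹

Brain tissue is homogeneous (1560 m/s, 1030 kg/m³, 0.34 dB MHz⁻¹ cm⁻¹);
water is 1480 m/s, 1000 kg/m³, 2.5e-5 dB MHz⁻¹ cm⁻¹.  Shear properties are
tied voxel-wise to the compressional ones: $c_s = (4/7)c_p$ and
$\alpha_s = (90/85)\alpha_p$ inside the skull mask, zero outside (the
ratios are global constants in the literature; voxel-wise application is
the only construction consistent with heterogeneous maps).  $B/A$ is 7.1
in tissue and skull and 5.2 in water.

Lamé constants follow $\mu = c_s^2\rho$, $\lambda + 2\mu = c_p^2\rho$.
The Kelvin-Voigt viscosities are $\eta = 2\rho c_s^3\,\alpha_s/\omega_0^2$
and $\chi + 2\eta = 2\rho c_p^3\,\alpha_p/\omega_0^2$ with $\alpha$ in
Np/m at the driving frequency: the $\omega^2$ factor is required
dimensionally by the standard low-loss Kelvin-Voigt relation, with the
consequence that absorption is exact at $\omega_0$ and quadratic in
frequency elsewhere — appropriate for the narrowband continuous-wave runs
used throughout.  A 1-D validation run recovers mapped attenuation within
a few percent over 20 cm of lossy bone.

**Acoustic absorption exponent.**  The acoustic solver's fractional-
Laplacian operator uses a frequency power law $\alpha_0\omega^y$ whose
prefactor is rescaled so absorption at the carrier matches the maps
exactly.  The dispersion part of the operator carries a
$\tan(\pi y/2)$ coefficient that diverges as $y \to 1$; with skull-grade
absorption (tens of dB MHz⁻¹ cm⁻¹) an exponent near 1 makes that term
dominate the equation of state and destabilizes the scheme.  The default
is therefore $y = 1.5$, and the operator's spectral filters are clamped
above three times the carrier wavenumber.  For single-frequency runs the
exponent only affects out-of-band content; in-band absorption is exact by
construction.  Runs whose total path attenuation is below $10^{-3}$ Np
(e.g. water-only runs) skip the operator (`absorption = "auto"`).

# Sources

Each array element is a baffled circular piston evaluated by the
discretized Rayleigh-Sommerfeld integral (face sampling at ≥ 6 points per
wavelength; verified against the closed-form on-axis solution to 0.5%).
Steering conjugates the water time of flight: with the package's
$e^{-i\omega t}$ phasor convention the emitted phase is
$-k(|x_i - x_t| - R)$.

The 30 cm array is reduced onto a fictitious hemispherical Huygens surface
(11 cm diameter at full scale) sampled at $\lambda/4$ on a spiral lattice.
Three details matter for quantitative agreement with the free field:

1. **Cap extension.**  Rays from rim elements to a steered target cross
   slightly *above* the equatorial plane; a bare half sphere clips them
   and loses about 5% of the focal amplitude.  The surface extends
   `cap_fraction = 0.15` of its radius above the equator.
2. **Obliquity.**  Each sample radiates as a monopole weighted by the
   cosine between the inward surface normal and the direction to the
   focus (the Rayleigh first-kind obliquity factor in its focal-direction
   approximation).
3. **Snap-phase re-projection.**  Mapping samples to voxel centres moves
   them by up to half a voxel diagonal — a large fraction of a wavelength
   on coarse grids — which destroys focusing coherence.  The sample phase
   is re-projected along the local propagation direction (toward the
   steering target) before injection.

Sources are injected additively into the mass balance.  Compact sources
(points, piston faces) are spatially band-limited first (radial
raised-cosine in $k$, flat through $1.25\,k_0$): a bare voxel delta
excites the whole discrete spectrum and leaves sinc truncation ringing
around the source.  The dense Huygens shell is injected unfiltered — its
superposition already concentrates in the propagating band, and the
filter's tail truncation across a quarter of the domain measurably
perturbs the beam wings.  With these measures the
solver reproduces the free-space monopole field within ~1% at
$\lambda/6.7$ spacing, and the reduced-surface run matches a direct
full-array simulation within 3% at the focus.  The first lateral
sidelobe of the reduced run sits ~10% (relative) above the full-array
reference — the intrinsic cost of re-radiating the surface pressure as
focal-direction-weighted monopoles rather than the full
monopole-plus-dipole layer; off-beam comparisons should keep this margin
in mind.

An optional geometric-optics restriction confines each element's
contribution to the cone from its aperture toward the focus
(`restrict = TRUE` in `project_to_surface()`); the default is the exact
unrestricted superposition.

# The synthetic phantom

The phantom is a spherical shell (default outer radius 35 mm, thickness
2.5 mm — a ~7 cm cranium) with an optional flat skull-base plate, and a
porosity texture $\psi = 0.3 + 0.15\,g(x)$ where $g$ is a unit-variance
Gaussian random field with 4 mm correlation length (spectral synthesis,
seeded).  Hounsfield units are $1000(1-\psi)$, so the porosity mapping
needs no clamping.  Mean porosity 0.3 gives mid-range skull properties
(c ≈ 2600 m/s, ρ ≈ 1840 kg/m³); the ±0.15 texture spans the porosity range
reported for cranial bone while keeping $\psi$ inside $(0,1)$ without
truncation for typical seeds.

What the phantom does *not* emulate: anatomical shape and thickness
variation, cortical/diploe layering, registration error, and CT
reconstruction-kernel effects.  Passing phantom-based tests therefore
shows that the *pipeline* responds to a heterogeneous aberrating skull the
way the method intends — not that animal-specific values are reproduced.

The device layout is a deterministic Fibonacci-spiral lattice (the
clinical array's element positions are proprietary).  With 1024 elements
on a 15 cm-radius hemisphere the minimum centre spacing is 10.25 mm, so
the default element radius is 5 mm (the largest radius compatible with a
non-overlap guarantee is 5.12 mm); with 1024 elements the focal field is
insensitive to the exact lattice.

# Metrics

The focal region is upsampled to 0.1 mm with a Catmull-Rom cubic
interpolant.  The max-pressure field is an amplitude *envelope* and is
not band-limited (it has kinks at nulls), so zero-padded spectral
upsampling rings and overshoots at the focal peak by several percent —
enough to suppress the normalized −3.5 dB volume by ~15%.  The cubic
interpolant passes through the samples without ringing; the spectral
method remains available (`method = "spectral"`) and is exact for
band-limited inputs, which its oracle test exercises.
Main-beam volumes (−3.5, −7 dB re peak) are integrated on the fine window;
side-lobe volumes (−12, −14 dB) are counted on the coarse grid over the
PML-free interior.  The peak is refined by a separable quadratic fit; peak
shifts are signed along the beam axis (negative = prefocal).  Voxels
inside the injected source shell carry a singular near field and are
excluded from peak searches and coarse volume counts.

dB-threshold conversions are exact arithmetic:
$p = p_{\mathrm{peak}}\cdot 10^{L/20}$.

# Aberration correction

Corrections are measured by reciprocity: a point source at the target is
propagated through the maps and the complex amplitude at each element
centre is extracted by a least-squares sinusoid fit over the trailing ten
cycles.  For arrays larger than the grid, the field is recorded on a
Huygens hemisphere inside the grid and propagated analytically through
water to the elements (`exterior = TRUE`).  Schemes: phase conjugation;
phase + amplitude (element drive ∝ 1/measured amplitude, equalizing focal
contributions, with elements above twice the mean required drive
excluded); phase + inverse amplitude (drive ∝ measured amplitude).  Total
power $\sum |w|^2$ is renormalized to the input drive power in every
scheme.

# PCD sensitivity

By reciprocity the receive sensitivity equals the normalized transmit
field of the detector, modelled as a spherically curved 40 × 7 mm
rectangle (15 cm curvature) of baffled Rayleigh monopoles, propagated
through the maps at the frequency of interest (grid requirement
$\Delta x \le \lambda/6$).  The combined map is the voxel-wise product of
the normalized detector and therapy fields; the intersection fraction is
the share of −6 dB therapy voxels inside the −6 dB combined region.
Microbubble emission is assumed linearly related to the local drive
pressure, so no bubble dynamics enter the map.

# Numerical choices and problem sizes

* Grid sizes are rounded to 5-smooth numbers for the internal mixed-radix
  FFT; `good_grid_size()` does this.
* The full-scale water reference run (acceptance targets) uses a
  144 × 144 × 108 grid at 1 mm, 120 µs, the 11 cm reduction surface and
  the steered target at (16, 0, 3) mm.  The −3.5/−7 dB volumes are
  compared with the study-scale values at ±15% (the element layout is
  approximated).  The solver's voxel values agree with the analytic
  Rayleigh field of the injected source set to ~1% there, which is the
  package's strongest end-to-end accuracy statement at this scale.
* Max-pressure recording starts after one domain crossing at the slowest
  map speed by default; continuous-wave fields make the recorded window
  insensitive to this choice near the beam.
* Test-suite scenarios are scaled (48³–108³ grids at 0.4–2 mm, arrays of
  64–128 elements with the device f-number) so the whole suite runs on one
  CPU in tens of minutes.  Property checks compare runs that share a grid,
  so common discretization biases cancel; absolute checks (Green's
  function, piston integrals, interface coefficients, attenuation rates)
  run at λ/5–λ/7 spacing where those biases are ~1–2%.
* The elastic fluid-limit check disables the acoustic solver's k-space
  correction and matches the CFL so both solvers share one time
  discretization; the comparison then isolates the elastic formulation
  itself (agreement to 1e-5).

# Known limitations

* Amplitudes at λ/3.4 sampling carry few-percent discrete-Green biases;
  quantitative absolute work should use λ/5 or finer (the paper-scale
  1 mm grid is λ/6.7 in water).
* The Kelvin-Voigt model is exact only at the driving frequency;
  broadband pulses would see quadratic-in-frequency absorption.
* No microbubble physics, thermal coupling, or registration; the phantom
  is geometric, not anatomical.
* The elastic solver's shear ratios are global constants; real trabecular
  bone varies, which biases side-lobe predictions (inherent to the
  modelling approach, surfaced as configuration knobs).
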