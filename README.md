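# skullwave

Full-wave simulation of transcranial focused ultrasound (FUS) for
microbubble-enhanced nonthermal brain ablation studies.

Low-frequency hemispherical FUS arrays can ablate deep brain targets
without heating by driving circulating microbubbles to inertial
cavitation, but prefocal side lobes of the beam can disrupt the
blood-brain barrier (BBB) and damage tissue outside the target.
`skullwave` implements the simulation pipeline needed to study these
effects: CT-derived material maps, phased-array source modelling, full
3-D wave propagation through the skull, and the beam/detector metrics
used to interpret them — exercised on a synthetic skull phantom so that
everything is reproducible without animal CT data.

## What is inside

* **Phantom** — a synthetic pseudo-CT cranium (spherical shell with a
  seeded porosity texture and an optional skull-base plate) plus the
  device geometry: 1024 circular-piston elements on a 30 cm hemisphere at
  220 kHz, and a weakly focused 40 × 7 mm passive cavitation detector
  (PCD).
* **Materials** — Hounsfield units → porosity `ψ = 1 − H/1000` → voxel
  maps: `c = 1480ψ + 3100(1−ψ)` m/s, `ρ = 1000ψ + 2200(1−ψ)` kg/m³,
  `α = 0.64 + 24.82·√ψ` dB MHz⁻¹ cm⁻¹, shear speed `(4/7)c_p`, shear
  absorption `(90/85)α_p`, and the Kelvin–Voigt coefficients
  `μ = c_s²ρ`, `λ + 2μ = c_p²ρ`, `η = 2ρc_s³α_s/ω²`,
  `χ + 2η = 2ρc_p³α_p/ω²`.
* **Sources** — Rayleigh piston integrals, time-of-flight steering, and
  reduction of the large array onto an 11 cm hemispherical Huygens
  surface that drives the solver.
* **Solvers** (C++ cores) — a first-order k-space pseudospectral acoustic
  solver (staggered grids, split-field PML, optional B/A nonlinearity and
  power-law absorption) and a Kelvin–Voigt viscoelastic solver capturing
  shear-mode conversion in bone.
* **Aberration correction** — point-source reciprocity measurement and
  the phase / phase+amplitude / phase+inverse-amplitude schemes at
  constant array power.
* **Metrics** — sub-voxel focal interpolation to 0.1 mm, iso-dB beam
  volumes (−3.5/−7 dB main beam, −12/−14 dB side lobes), signed focal
  shifts, dB→pressure conversions, harmonic spectra.
* **PCD** — receive-sensitivity maps by reciprocity and the fraction of
  the −6 dB focal volume the detector actually sees.

The methods vignette (`vignettes/methods.Rmd`) documents the governing
equations, the numerical choices and the phantom's limitations.

## Worked example

A water-only run of the full steered device (the reference row of the
beam-volume table):

```r
library(skullwave)

cfg <- run_config(phantom = NULL,                      # water only
                  grid_dims = c(144, 144, 108), spacing_mm = 1,
                  grid_origin_mm = c(-71.5, -71.5, -78),
                  duration_us = 120,
                  steering_mm = c(16, 0, 3))           # lateral/axial steering
out <- run_scenario(cfg)
out$metrics[c("x_mm", "y_mm", "z_mm", "vol_3.5dB_mm3", "vol_7dB_mm3")]
```

```
  x_mm y_mm z_mm vol_3.5dB_mm3 vol_7dB_mm3
  16.1    0    3        35.228      90.914
```

The focus lands at the steering target (16, 0, 3) mm to within a voxel;
the −3.5 dB volume (≈ 35 mm³, the observed lesion scale) and the −7 dB
volume (≈ 91 mm³) characterize the main beam, while the −12/−14 dB
columns of the same table measure the side-lobe region implicated in
prefocal BBB disruption.  Converting thresholds to absolute pressure at
an experimental 415 kPa peak:

```r
db_to_pressure(415, c(-3.5, -14, -15))
#> [1] 277.33  82.78  73.80     # kPa: lesion edge, BBB disruption limits
```

The numbered scripts under `analysis/` run the comparative scenarios on
the scaled phantom (acoustic vs elastic, aberration-correction schemes,
skull-base removal, nonlinear harmonics, steering cost, PCD sensitivity)
and write their tables under `results/`.

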