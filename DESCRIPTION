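Package: skullwave
Title: Transcranial Focused Ultrasound Field Simulation with k-Space
    Pseudospectral Solvers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Full-wave simulation of transcranial focused ultrasound for
    microbubble-enhanced nonthermal brain ablation studies.  Provides a
    synthetic skull-phantom generator, CT Hounsfield-unit to acoustic and
    viscoelastic material mapping via a porosity model, Rayleigh-integral
    modelling of hemispherical phased arrays with Huygens surface-source
    reduction, linear and nonlinear k-space pseudospectral acoustic solvers
    and a Kelvin-Voigt viscoelastic solver with shear-mode conversion,
    phase and amplitude aberration-correction schemes, focal beam metrics
    (iso-dB volumes, peak shift, harmonic content), and passive cavitation
    detector sensitivity mapping by acoustic reciprocity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
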