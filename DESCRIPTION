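Package: gliosim
Title: Image-Driven Reaction-Diffusion Simulation of Glioblastoma Growth and Necrosis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-difference simulation of glioblastoma multiforme progression
    on voxel grids: anisotropic tumor cell migration guided by a diffusion
    tensor field, logistic (or exponential/Gompertz) proliferation, and a
    threshold-triggered, history-dependent necrosis term. Includes estimation
    of the proliferation rate and mean cell diffusivity from serial T1/T2
    tumor radii via the Fisher traveling-wave relation, derivation of the
    cell diffusion tensor from a spin diffusion tensor by differential
    eigenvalue scaling, calibration of the necrosis threshold and rate from
    imaging features, mutual-information comparison of simulated density
    fields against (pseudo-)images, and synthetic tensor-field phantoms so
    that every pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
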