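Package: periflow
Title: Two-Phase Blood Flow and Protein Recruitment around Textured Dental Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational model of early blood and fibrinogen
    recruitment into the peri-implant gap of a screw-shaped dental implant.
    Builds a 2D cross-sectional implant/bone domain with three surface
    topographies (amorphous, nano-trabecular, hybrid meso-nano), computes
    areal roughness metrics (Sa, Sz, Sdr), simulates transient two-phase
    volume-of-fluid filling with surface tension and texture-dependent
    wetting, transports fibrinogen as a passive scalar in the liquid phase,
    and reports zone-resolved recruitment metrics (interface, thread, outer
    zones), recruitment efficiency, and topography comparisons. Includes
    closed-form validation benchmarks (Poiseuille, static droplet,
    Gaussian diffusion, capillary channel) and a coarse mini-implant
    experiment runnable on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
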