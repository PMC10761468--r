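Package: musmb
Title: Simulation and On-Line Mass-Spectrometric Monitoring of Micro
    Simulated-Moving-Bed Desalting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation of a four-zone open-loop micro
    simulated-moving-bed (SMB) size-exclusion desalting process coupled to a
    native electrospray mass-spectrometry (ESI-MS) detector model. Provides
    literature transport correlations (Chung-Wen axial dispersion,
    Wilson-Geankoplis film transfer, Polson diffusivity), a finite-volume
    lumped-rate-model-with-pores column simulator, triangle-theory operating
    point design, port-switching SMB simulation with cyclic-steady-state
    detection and desalting metrics, a synthetic native ESI spectrum generator
    (charge envelopes, sodium adducts, buffer suppression), and the standard
    MS post-processing chain (extracted-ion chromatograms, baseline traces,
    zero-charge protein reconstruction, apo-protein percentage). A
    synthetic-data module generates complete in-silico desalting experiments
    with detector noise for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
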