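Package: atriawave
Title: Multiscale Simulation of Human Atrial Electrophysiology and Reentry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ionic models of the human atrial cardiomyocyte (Courtemanche-1998 and
    the Grandi-2011 sinus-rhythm atrial model) behind a common right-hand-side
    contract with per-current conductance scaling, single-cell pacing and
    action-potential biomarker extraction, conductance-sensitivity scans, a 2D
    isotropic monodomain tissue solver with S1S2 cross-field reentry induction,
    vulnerable-window classification, phase-singularity rotor tracking, and
    chronic/acute conductance-intervention experiments for atrial-fibrillation
    electrical remodeling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
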