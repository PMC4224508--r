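Package: nodalsim
Title: Reaction-Diffusion and Cellular-Automaton Simulation of the
    Cardiac Conduction System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for the electrophysiology of the right
    atrium and its conduction system (sinoatrial node, atrial muscle,
    inferior nodal extension, penetrating bundle, passive block zone).
    Provides modified FitzHugh-Nagumo reaction-diffusion kinetics with
    fiber-based anisotropic diffusion tensors on voxel label volumes, a
    three-state cellular-automaton conduction engine, synthetic geometry
    generators (strand, slab, idealized two-dimensional right atrium,
    dual-pathway ring), stimulus protocols (S1-S2 restitution, sinus
    rhythm, fibrillation-like reentry, echo beats) and the standard
    electrophysiological measurements (conduction velocity, action
    potential duration at 90 percent repolarization, maximum upstroke
    velocity, refractory period, cycle length, conduction-block ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
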