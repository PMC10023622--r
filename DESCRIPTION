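Package: trimorph
Title: Tricuspid Valve Morphometry and Right-Heart Hemodynamics for an Ex
    Vivo Regurgitation Model
Version: 1.0.0
Authors@R:
    person("trimorph", "developers", email = "trimorph@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for an ex vivo beating-heart model of
    functional tricuspid regurgitation. Implements 3D-echocardiography-style
    tricuspid annulus morphometry (fourth-order Fourier annulus fitting,
    best-fit-plane projection, perimeters, areas, diameters, Delaunay leaflet
    surface reconstruction and tenting volume), semi-automatic right-ventricle
    volumetry (speed image, seeded region growing, scripted refinement),
    pulsatile and steady hemodynamic indexes (regurgitant fraction, cardiac
    output, pulmonary regurgitant volume, steady backflow) with a
    three-element Windkessel pulmonary impedance simulator, synthetic valve
    and ventricle phantoms with closed-form ground truth, and a paired
    fresh-versus-defrosted cohort comparison with Table-style reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
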