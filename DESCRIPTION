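Package: earfield
Title: Ear-Augmented Boundary-Element Forward Models for Ear-EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of ear-augmented multi-shell
    boundary-element (BEM) head models for ear-EEG. Provides triangulated
    surface mesh handling (STL/PLY/OFF), rigid fiducial registration of
    earpieces and digitized landmarks, carving of ear-impression volumes out
    of the scalp surface with a minimum inter-surface distance rule, a linear
    collocation BEM forward solver with the isolated problem approach (IPA)
    for the low-conductivity skull, lead field matrices on a Cartesian source
    grid, single equivalent-current-dipole fitting of component maps with
    residual variance, group-wise Pearson correlation and PVAF metrics, lead
    field sensitivity distributions for arbitrary electrode configurations,
    multi-amplifier recording preprocessing (alignment, resampling,
    referencing, filtering, saturation and auditory steady-state response
    based channel rejection), and synthetic concentric-sphere and
    ear-augmented head fixtures with an analytic multilayer-sphere oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
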