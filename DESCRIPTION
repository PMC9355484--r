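Package: leafphys
Title: Leaf Gas Exchange, Chlorophyll Fluorescence and Photosynthesis Model Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf-level ecophysiology experiments on C3
    crops: pulse-amplitude-modulated (PAM) chlorophyll-fluorescence calculus
    with PSII energy partitioning (Fv/Fm, PhiPSII, PhiNPQ, PhiNO, qP, qL,
    NPQ, ETR), derived stomatal indices (intrinsic water-use efficiency,
    Ci/Ca, stomatal limitation), fluorescence-based Rubisco carboxylation and
    oxygenation velocities, Farquhar-von Caemmerer-Berry A/Ci curve fitting
    with limitation-state assignment (Vcmax, Jmax, TPU, Rd), light-response
    curve fitting with SSE-based model selection and cardinal points (Ic, Ik,
    quantum yield, Pmax, Amax), a factorial randomized-complete-block ANOVA
    layer with Fisher's protected LSD and pooled-SEM reporting, and a
    synthetic-experiment generator for end-to-end parameter-recovery testing
    of waterlogging-type two-cultivar by two-treatment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
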