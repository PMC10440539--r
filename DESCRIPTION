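Package: vesselfem
Title: Multilayer Coronary Vessel Thin-Slice Finite-Element Stress Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing multilayer (intima/media/adventitia) and
    single-layer coronary plaque biomechanics on image-derived cross-sections.
    Provides a contour data model for segmented vessel slices with lipid and
    calcification inclusions, a synthetic cohort generator emulating
    intravascular OCT segmentation output, anisotropic hyperelastic
    (modified Mooney-Rivlin with an exponential fiber term) constitutive
    models with layer-specific parameters, circumferential pre-shrink and
    axial shrink-stretch recovery of the computational start shape, a
    nonlinear nearly-incompressible finite-element solver for 0.5 mm
    thin-slice inflation, a semi-analytic layered-cylinder verification
    oracle, quarter-dividing stress/strain extraction at the lumen, cap and
    out-wall, and paired comparison statistics across a patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
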