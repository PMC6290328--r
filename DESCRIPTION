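Package: gubquant
Title: Quantitative Imaging, Mechanics and Morphometry of the Fetal Gubernaculum
Version: 0.1.0
Authors@R:
    person("Gubernaculum", "Analysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable analysis pipeline for regional quantification of
    androgen-receptor immunofluorescence in cleared fetal gubernaculum
    confocal volumes, micropipette-aspiration estimation of the apparent
    elastic modulus with regional and gestational comparisons, and
    muscle-fiber morphometry with background filtering. Includes a
    ground-truthed synthetic-data generator (confocal phantoms, forward
    mechanical cohorts, fiber tables) used to validate every stage, a
    minimal multi-page TIFF reader/writer with physical voxel spacing,
    3D image filters (anisotropic median, plane-wise rolling-ball
    background subtraction, grayscale ellipsoidal closing, hysteresis
    thresholding), and a self-contained statistical toolbox (one- and
    two-way ANOVA, pooled/Welch t, exact Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
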