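Package: tirfpharm
Title: TIRF Puncta Quantification and Receptor Pharmacology Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies beta-arrestin membrane recruitment in total internal
    reflection fluorescence (TIRF) microscopy images via a grayscale-morphology
    pipeline (square-root intensity transform, Gaussian smoothing, dual top-hat
    background suppression, non-maximal-suppression peak finding,
    marker-controlled watershed, Otsu cell segmentation) and carries its
    per-cell endpoints through the matching statistical layer (variance
    stabilization, Bartlett, one-way ANOVA, Monte-Carlo Dunnett,
    Benjamini-Hochberg). Companion receptor-pharmacology tools cover
    four-parameter logistic dose-response fitting, HTRF cAMP standard-curve
    interpolation, percent desensitization, potency shifts, Cheng-Prusoff Ki,
    apparent Kb, PK-driven receptor occupancy projection, and a hierarchical
    Bayesian saturation-binding model that classifies competitive versus mixed
    inhibition. A ground-truthed synthetic-data generator emulates TIRF fields,
    dose-response plates, radioligand binding counts and one-compartment PK
    profiles so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
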