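Package: pyrasense
Title: Odor Activity Values and Perceptual Interactions of Pyrazines in Baijiu
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Chemosensory analysis of pyrazines in soy sauce aroma type
    Baijiu: targeted-quantitation quality control (calibration linearity,
    recovery, replicate RSD, LOD/LOQ), odor activity value (OAV) profiling
    with sub-/supra-threshold banding, Spearman screening of compound
    concentrations against descriptive-panel roasted-aroma intensity,
    exact 3-alternative forced-choice discrimination testing with Abbott
    chance correction, group odor-threshold estimation on geometric
    dilution series (isotonic smoothing plus log-dose interpolation, or a
    guessing-floor logistic fit), and detection of perceptual synergy
    between sub- and supra-threshold odorants under Feller's additive
    model. Ships the published concentration/threshold tables as plain-text
    fixtures and a full synthetic-data generator so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: MassSpectrometry, Metabolomics, QualityControl, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
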