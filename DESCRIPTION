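Package: fluoroscreen
Title: Melt-Curve Scoring and Spectral Discrimination for Fibril-Binding Fluoroprobe Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput discovery of fluorescent
    dyes that recognize amyloid fibril polymorphs. Implements threshold-rule
    scoring of protein-adaptive differential scanning fluorimetry (paDSF)
    melt curves with replicate aggregation and control-based hit triage,
    excitation/emission scan-grid construction with adaptive-threshold
    particle segmentation and PCA plus quadratic-discriminant polymorph
    discrimination for multispectral confocal image stacks, normalization and
    timing metrics for real-time aggregation kinetics, Tanimoto fingerprint
    diversity summaries, and seeded synthetic-data generators that emulate
    the screen's statistical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
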