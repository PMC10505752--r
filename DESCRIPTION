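Package: ihcTASC
Title: Quantitative DAB Immunohistochemistry and Target Suitability Scoring
        for Soft Tissue Sarcoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Pixel-intensity-level quantification of DAB (diaminobenzidine)
        immunohistochemistry for fibroblast activation protein alpha (FAP)
        in human, canine, and feline soft tissue sarcoma. Implements
        five-level intensity classification of brightfield images, rule-based
        artifact exclusion, per-region area measurement normalized to 10
        high-power fields (2.37 mm^2), mean staining intensity, a
        semiquantitative expression score (percentage score times intensity
        score), tumor-to-normal ratio computation, and the seven-criterion
        target selection criteria (TASC) rubric for imaging-target
        suitability. Includes a seeded synthetic-image and synthetic-cohort
        generator with exact ground truth so the full pipeline is testable
        without external slide data, plus nonparametric group comparison,
        correlation, and categorical reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, png, yaml, jsonlite, tools
Suggests: testthat (>= 3.0.0), tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
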