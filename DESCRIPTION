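Package: fuccicycle
Title: FUCCI-Based Cell-Cycle Analysis for Cardiomyocyte Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-color FUCCI (fluorescence ubiquitination
    cell cycle indicator) imaging of cardiomyocytes: nuclei segmentation and
    background-subtracted intensity measurement, four-state FUCCI classification
    (blue/red/yellow/green), single-cell time-lapse trace analysis separating
    division, binucleation and G2-arrested polyploidization with S/G2/M duration
    estimation, plate-based compound-screen scoring with site and treatment QC and
    percent-of-control normalization, and DNA-content ploidy and binucleation
    analysis. Includes a synthetic-data generator that emulates the imaging study
    end to end (fate-labelled traces, rendered snapshot images, screening plates,
    ploidy populations) so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
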