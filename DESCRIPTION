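Package: capstall
Title: Quantitative Analysis of Targeted Capillary Photothrombosis Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing targeted single-capillary photothrombosis
    experiments performed by multiphoton excitation of a circulating
    photosensitizer. Covers multiphoton photophysics characterisation
    (excitation-order fits, reference-ratio two-photon cross sections, focal
    fluence estimates), red-blood-cell flux and speed extraction from
    line-scan kymographs with motion-artifact rejection, stall and blockage
    calling under a minimum no-flow-duration rule with verification scans,
    angiography perfusion maps by high-pass temporal filtering with
    background-normalised stallograms and longitudinal occlusion tracking,
    tissue-to-nearest-vessel distance maps with before/after histogram
    comparison, and group-level occlusion statistics (incidence rates and the
    pooled two-proportion z-test). A seeded synthetic-data module emulates
    every input modality with retained ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    withr,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
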