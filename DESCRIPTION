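Package: clsscreen
Title: Chronological Lifespan Screening from Propidium-Iodide Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide chronological lifespan (CLS) screens in
    fission yeast scored by propidium-iodide flow cytometry. Converts raw
    per-well event tables into gated viability fractions, assembles survival
    curves normalised to the logarithmic-phase sample, scores longevity as
    the area under each survival curve, and classifies deletion strains as
    average, short- or long-lived by maximum posterior probability against
    Student-t predictive distributions fitted to on-plate control strains.
    Includes a synthetic screen generator with known ground truth for
    validation, hypergeometric gene-set enrichment over GMT collections,
    and degree-of-oxidation computation for ratiometric H2O2 probes measured
    on dual-excitation plate readers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
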