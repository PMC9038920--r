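Package: qsipdom
Title: Quantitative Stable Isotope Probing and FT-ICR-MS Dissolved
    Organic Matter Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two quantitative inference chains used in marine
    microbial carbon-cycling studies. The qSIP chain converts paired
    labeled/unlabeled cesium-chloride density-gradient qPCR profiles into
    excess atom fraction 13C per marker gene, via weighted mean buoyant
    density, GC content, and per-nucleotide molecular weight. The DOM
    chain assigns CHNOSP molecular formulas to negative-mode FT-ICR-MS
    peak lists under element-count constraints, computes the modified
    aromaticity index and a nine-class van Krevelen compound
    classification, derives intensity-weighted molar ratios, and compares
    samples by Bray-Curtis dissimilarity and principal coordinates
    analysis. Seeded synthetic-data generators with serialized ground
    truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
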