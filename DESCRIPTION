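Package: msiNiche
Title: Niche Segmentation and Ecological Diversity Analysis for Spatial
    Metabolomics of Plasma-Cell Disorders
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing mass-spectrometry-imaging (MSI)
    metabolomics of bone-marrow biopsies together with matched bulk
    bone-marrow plasma profiles across the MGUS to multiple-myeloma
    continuum. Implements total-ion-current normalisation and bisecting
    k-means niche segmentation of pixel-level metabolite images,
    plasma-cell-rich niche calling with concordance against pathology
    plasma-cell percentage, assumption-routed two-group differential
    statistics with Benjamini-Hochberg control, tissue-by-plasma
    fold-change directional classification with pathway tallies,
    metabolite-proliferation coupling with a segmentation-gain statistic,
    a Hill-number (q = 2) diversity framework (within-niche evenness,
    paired two-community beta diversity, Cliff's delta, HC3-robust
    regression), PERMANOVA and PLS-VIP multivariate summaries, and a
    synthetic cohort generator emulating the two-compartment spatial
    structure of precursor and malignant bone marrow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    car,
    sandwich,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
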