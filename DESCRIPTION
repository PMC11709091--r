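Package: poolfrac
Title: Pooled-Plasma Extracellular Vesicle and Protein-Fraction Proteomics
    Analysis via Ratio-Sign-Consistency Differential Abundance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled blood-plasma proteomics in which
    size-exclusion chromatography separates an extracellular-vesicle (EV)
    enriched fraction from a free-protein (PROT) fraction. Implements
    detection-rate filtering, the ratio-sign-consistency differential
    abundance rule for paired fraction and cross-group (age, sex)
    comparisons with analytic null-rate calculators, set-intersection
    triage of age-dynamic and sex-consistent proteins, marker-panel
    characterization, particle-concentration normalization, Fisher's LSD
    group statistics, and hierarchical clustering. Ships a synthetic-data
    generator that emulates a six-group (sex by age) donor-to-pool study
    design so every stage is testable without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
biocViews: Proteomics, DifferentialExpression, Clustering, Software
RoxygenNote: 7.3.3
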