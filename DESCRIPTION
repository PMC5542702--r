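Package: AedesResist
Title: Insecticide Resistance Phenotyping and Multi-Contrast Expression
    Analysis for Aedes aegypti Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for characterising insecticide resistance in
    Aedes aegypti field populations: WHO tube-bioassay mortality summaries
    with Abbott correction and resistance classification, synergist
    restoration tests, enzyme-activity comparisons, a replication-criterion
    differential-expression caller for multi-contrast two-colour microarray
    log-ratios with an analytic expected-false-positive calculator, Pfaffl
    efficiency-corrected qRT-PCR quantification with dual reference-gene
    normalisation, and knockdown-resistance (kdr) genotype frequency and
    association analysis based on exact contingency tests. Includes
    synthetic-data generators emulating every input so the whole pipeline
    can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, Microarray, DifferentialExpression,
    StatisticalMethod, qPCR, SNP
RoxygenNote: 7.3.3
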