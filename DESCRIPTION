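Package: acidflux
Title: Bioenergetic Budgets and Transcriptome Post-Processing for
    Acidosis-Treated Vascular Smooth Muscle Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of lactic- versus hydrochloric-acidosis
    experiments on vascular smooth muscle cells: calibration-curve
    quantification of plate-reader assays, substrate flux normalization,
    Mito-Stress oxygen-consumption parameter extraction, a stoichiometric
    ATP budget partitioning glycolytic and oxidative production, and
    post-processing of differential-expression tables (threshold filtering,
    three-set Venn partitioning, sign concordance with regression slope,
    and hypergeometric gene-set enrichment with a fold-enrichment filter).
    A seeded synthetic-experiment generator emulates the five-condition
    design with known ground truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'assay-quant.R'
    'bioenergetics.R'
    'atp-budget.R'
    'transcriptome.R'
    'enrichment.R'
    'io.R'
    'phenotype.R'
    'rank-tests.R'
    'synthetic-design.R'
    'synthetic-degs.R'
    'synthetic-ocr.R'
    'synthetic-plates.R'
    'pipeline.R'
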