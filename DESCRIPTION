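Package: p53screen
Title: Pooled shRNA Screen Quantification and TP53-Stratified Prognostic
    Gene Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for isolating prognostic factors that act through the
    p53 pathway by combining a pooled shRNA drop-out/enrichment screen with
    genotype-stratified survival analysis of tumour expression cohorts.
    Quantifies shRNA barcode abundance from FASTQ reads or count tables,
    classifies shRNAs and genes as drug-sensitive or drug-resistant by
    treated/control fold change, applies per-sample microarray quality
    control, estimates Kaplan-Meier curves and two-group log-rank tests
    from the product-limit definition, scans every probe for survival
    association within TP53 wild-type and mutant strata after a median
    split, intersects screen hits with genes prognostic in wild-type but
    not mutant tumours, and tests the resulting gene list for gene-set
    over-representation. Includes seeded simulators for every input so the
    whole pipeline is testable with planted ground truth, plus Poisson
    multiplicity-of-infection utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
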