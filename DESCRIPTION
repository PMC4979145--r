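Package: rfikit
Title: Residual Feed Intake Genetics: Growth Curves, REML, GWAS, LD Blocks
    and Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for quantitative-genetic analysis of
    residual feed intake (RFI) in meat-type poultry. Fits per-bird linear
    growth curves to derive average daily gain and metabolic mid-test body
    weight, computes RFI as the residual of the Koch intake model, estimates
    heritability and genetic correlations by restricted maximum likelihood
    with a genomic or pedigree relationship matrix, runs a kinship-adjusted
    single-marker association scan with genomic control and chromosome-wise
    false discovery rates, builds D-prime confidence-interval haplotype
    blocks, calls RPKM-based differentially expressed genes between
    RFI-divergent groups, and integrates association hits with annotation
    and expression. A synthetic-data generator with ground-truth labels
    supports calibration and testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    vcfR,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
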