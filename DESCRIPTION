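Package: genepyr
Title: Per-Individual Gene-Level Pathogenicity Burden Scores
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes GenePy-style per-gene, per-individual pathogenicity
    burden scores from multi-sample VCF data. Each observed variant is
    weighted by an in-silico deleteriousness metric (sixteen supported,
    normalised to a common 0-1 scale), its population allele frequency and
    the sample's zygosity, and variant scores are summed within genes.
    Includes capture-kit target-region harmonisation with per-gene targeted
    lengths and gene-length correction, rank-sum case/control comparison of
    score distributions (full distributions and extreme tails), per-gene
    Z-score patient profiles, and a self-contained synthetic-cohort
    generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
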