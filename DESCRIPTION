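Package: cnvroh
Title: Post-Analysis of Copy Number Variants and Runs of Homozygosity from SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A one-stop post-analysis toolkit for SNP-array-derived copy number
    variants (CNV) and runs of homozygosity (ROH): standardization of caller
    output (PennCNV, CNVPartition), summary tables, copy number variation
    region (CNVR) calling by closed-interval union merge, gene annotation with
    sample-frequency weighting, population- and individual-level interval
    comparison, SNP-anchored coordinate liftover between assemblies,
    ROH-based inbreeding coefficients (F_roh), high-frequency region
    detection, and haplotype/diplotype frequency extraction from phased
    genotypes.  Includes seeded synthetic-cohort generators with planted,
    recoverable structure for offline end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    vcfR,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
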