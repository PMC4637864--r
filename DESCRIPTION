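Package: ccqtl
Title: QTL Mapping and Cross-Trait Pleiotropy Analysis for Multiparental
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative trait locus
    (QTL) mapping in multiparental recombinant inbred mouse panels such as
    the Collaborative Cross. Simulates inbred strains as mosaics of eight
    founder haplotypes, projects biallelic markers through founder
    strain-distribution patterns, and generates correlated two-trait
    phenotypes with planted (partly pleiotropic, opposite-sign) loci, sex
    effects and replicate noise. Provides a single-marker genome scan with
    Benjamini-Hochberg FDR classification, run-based QTL interval calling,
    cross-trait QTL overlap and effect-direction analysis, and
    gene-to-interval enrichment against external gene lists, together with
    plain-text readers/writers and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
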