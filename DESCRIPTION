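Package: apygwas
Title: Single-Step GWAS by APY Inversion and Sliding-Window Variance Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for genome-wide association from genomic estimated
    breeding values (GEBVs) in large genotyped cattle populations: marker
    quality control (call rate, minor allele frequency, Hardy-Weinberg
    heterozygote deviation, autosome restriction), VanRaden genomic
    relationship matrix construction with identity blending, core selection
    and inversion via the Algorithm for Proven and Young (APY), back-solving
    of per-SNP effects from GEBVs through the APY inverse, sliding-window
    partitioning of the additive genetic variance with effective-population-
    size-based window sizing, and positional candidate-gene annotation.
    Includes a gene-dropping simulator producing genotypes, QTL effects,
    phenotypes and GBLUP GEBVs so that every stage is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
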