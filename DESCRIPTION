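Package: recscan
Title: Recessive Lethal Haplotype Discovery from Phased SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide discovery of deleterious recessive haplotypes in
    livestock from phased SNP-array data. Provides a sliding-window
    haplotype homozygosity-deficiency scan with binomial testing and
    Benjamini-Hochberg FDR control, merging of significant windows into
    risk regions, Hardy-Weinberg deficit and segregation tests on genotype
    counts, embryonic-mortality contrasts from artificial-insemination
    return records, multi-criterion candidate-variant prioritization with
    haplotype-variant linkage disequilibrium, splice-boundary sequence-logo
    construction from a genome and GTF, and a synthetic-data generator that
    reproduces the statistical structure of a survivor census carrying a
    recessive lethal haplotype.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
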