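Package: diagsnp
Title: Discovery and Validation of Species-Diagnostic SNP Markers from
    Reduced-Representation Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying species-diagnostic single nucleotide
    polymorphism (SNP) markers from multi-species diploid genotype matrices
    such as those produced by ddRAD-seq pipelines. Implements shared-locus
    filtering (polymorphism, per-sample presence, biallelic restriction,
    SNPs-per-locus caps), one-vs-rest fixed-difference marker discovery over
    any taxon set, pairwise diagnostics, assay-design candidate filtering and
    panel selection; validation via per-taxon diagnostic-allele frequency
    tables, marker specificity classification and cross-platform genotype
    concordance with mismatch typing; exports of composite-genotype
    alignments, genotype PCA, allele-sharing distances, neighbor-joining
    trees and BED marker maps; and a seeded synthetic genotype generator
    with planted diagnostic markers, RAD-style heterozygote dropout and a
    second-platform replicate for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
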