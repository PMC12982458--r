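Package: mnpkit
Title: Multiple Nucleotide Polymorphism Marker Panels for Cultivar
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and deployment of multiple nucleotide polymorphism
    (MNP, microhaplotype-style) amplicon marker panels for DNA
    fingerprinting of plant cultivars. Screens population SNP genotypes
    with a sliding-window scan for tightly linked, highly discriminating
    SNP clusters, assembles a genome-spaced amplicon panel, genotypes
    accessions from amplicon reads by haplotype-sequence allele calling,
    and computes the identification statistics used in cultivar
    fingerprinting: detection rate, genetic similarity, reproducibility
    and accuracy, polymorphism information content, molecular ID codes,
    UPGMA clustering and principal coordinates analysis. A synthetic-data
    simulator generates complete reference/VCF/FASTQ fixtures with known
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
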