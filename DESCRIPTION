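Package: allokaryo
Title: Subgenome Content, Karyotype, and Parental Origin of Hybrid Yeast
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes interspecies yeast hybrids (e.g. Saccharomyces
    cerevisiae x S. eubayanus lager hybrids) from variant calls and binned
    read-depth tracks obtained by competitive mapping to a chimeric
    two-subgenome reference. Computes covered-nucleotide proportions and
    the Se/Sc mapping ratio, calls the mitotype from mitochondrial
    coverage dominance, infers per-chromosome integer copy number by
    combining alternate-allele-frequency modality with quantized depth,
    reports aneuploidies (duplications and deletions) against the modal
    karyotype, and traces the parental origin of each chromosome through
    homozygous private parental SNPs. A synthetic-data module simulates
    allopolyploid hybrids with known truth so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
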