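Package: hlatyper
Title: HLA Genotyping from Short-Read Sequencing by Comprehensive
    Reference Mapping, Zero-Mismatch Assembly and Stepwise Allele
    Designation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Types highly polymorphic HLA class I and class II genes from
    whole exome or whole genome short reads. Reads are classified to genes
    by mapping against a comprehensive reference panel holding every known
    allele's polymorphic exons with 50 bp intron flanks plus competitor
    genes, assembled per gene into contigs admitting only overlaps with
    100 percent identity, and matched exactly to major- and additional-exon
    allele databases with G-group collapsing. Alleles are designated by a
    descending-score walk over contig evidence, G-groups are resolved to
    six digits via minor exons, phase ambiguity between heterozygous blocks
    separated by identical runs longer than the read length is enumerated
    and broken by population frequency, and calls carry per-exon coverage
    quality tiers. Includes a mock allele-database and read simulator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
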