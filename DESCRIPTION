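Package: cpkit
Title: Chloroplast Genome Finishing, Intra-Species Polymorphism Survey, and
    Cultivar Authentication Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reference-anchored finishing of circular chloroplast
    (plastid) genomes and 45S ribosomal DNA units from overlapping shotgun
    contigs, for surveying rare intra-species SNP/InDel polymorphism and
    tandem-repeat copy-number variation across cultivar cohorts, and for
    turning the discovered polymorphisms into genotyping assays: InDel size
    markers, dCAPS (derived cleaved amplified polymorphic sequence) designs,
    in-silico PCR and restriction digestion, and cultivar-authentication
    matrices. Includes a fully specified synthetic-cohort generator (quadripartite
    plastome with inverted repeats, cultivar haplotypes, nrDNA units, contigs
    and paired-end reads) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
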