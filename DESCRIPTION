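Package: genolite
Title: Embedded Genome Store with Lazily Computed Variant-Personalized
    Transcript and Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An embedded, single-file genome and proteome exploration
    store for precision-medicine workflows. Reference genomes (FASTA +
    Ensembl-style GTF) and polymorphism sets (VCF or dbSNP-like tables)
    are imported from packaged "datawraps" into one store file, queried
    through a single get_records() interface that serves minimal lazily
    inflating singleton records, and combined with user-supplied allele
    filters into personalized genomes that materialize subject-specific
    transcript and protein sequences on demand (filter, insert, assemble,
    translate). Ships a deterministic synthetic-datawrap generator with an
    independent naive oracle so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
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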