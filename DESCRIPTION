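Package: IntronProfiler
Title: Positional Profiling of Intronic Variants Flanking Exons in Exome Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Profiles called variants by their position within intronic
    regions flanking exons. Assigns each variant a symmetric splice-site
    offset (donor +d / acceptor -d collapsed to a bucket d), reimplements
    GATK-style hard filters and a frequency/clinical-significance/in-silico
    deleteriousness cascade, aggregates per-position counts, false-variant
    proportions and sequencing depth, and tests positional differences with
    paired t-tests, Fisher's exact tests and a noncentral-t power
    computation. Includes a seeded synthetic exome-cohort generator with a
    per-position truth table so the whole pipeline can be exercised and
    validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    data.table,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
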