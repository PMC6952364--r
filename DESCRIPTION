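Package: JunctionWalker
Title: Annotation-Free Alternative Splicing Event Discovery from Splice-Junction Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers binary alternative-splicing events (cassette exons,
    alternative splice-site exon groups, linked exons, and mutually exclusive
    exon pairs) directly from splice-junction count tables by a junction-walking
    strategy, without any transcript annotation. Quantifies percent spliced-in
    (PSI) per event per sample with an explicit missing-data policy, summarizes
    PSI by sample group, calls group-specific exons, flags event exons as
    annotated or unannotated against a GTF, and profiles splice-site motif
    enrichment in intronic and exonic windows around event exons. Includes a
    fully seeded synthetic-data generator (junction tables, genomes,
    annotations, planted motifs) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'event-discovery.R'
    'junctions-io.R'
    'motifs.R'
    'pipeline.R'
    'psi.R'
    'specificity.R'
    'synthetic.R'
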