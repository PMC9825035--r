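Package: organellotype
Title: Organelle Genome Polymorphism, Haplotype and Heteroplasmy Analysis
Version: 0.1.0
Authors@R: person("Organellotype", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for polymorphism and haplotype analysis of
    plant organelle (chloroplast and mitochondrial) genomes from
    multi-sample variant calls. Detects duplicated regions of a circular
    genome by self-comparison and masks variants inside them, classifies
    variants (SNP/InDel, bi-/multi-allelic, Ts/Tv) and annotates coding
    effects against gene models, reduces polymorphic sites to tag sites by
    perfect linkage, assigns and frequency-ranks haplotypes, builds minimum
    spanning haplotype networks and distance-based haplotype groups, joins
    chloroplast and mitochondrial haplotypes into cytoplasm types with
    geographic composition and diversity summaries, and measures
    heteroplasmy-like signal as per-accession reference allele frequencies
    from allele depths. Ships a synthetic-data generator that plants fully
    known truth (references, gene models, panels, VCFs) so every stage has
    a recovery test without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
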