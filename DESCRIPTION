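Package: exertome
Title: Exercise Transcriptome Analysis: Unigene Clusters, Filtered SNV
    Discovery, Voting Differential Expression and Isoform Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable re-implementation of a multi-sample, paired-design
    RNA-Seq analysis pipeline for a six-animal, two-tissue, before/after
    exercise study. Clusters per-sample transcript models into unigene
    clusters (maximal same-strand, exon-overlapping groups across samples)
    and classifies them against a reference annotation with an open reading
    frame length filter; calls single-nucleotide variants and short indels
    from per-sample site observations with stringent depth, allele-fraction
    and exon-intron boundary misalignment filters, merges them into a
    non-redundant set, compares them with two SNP databases and annotates
    coding effects; quantifies expression as FPKM and calls differentially
    expressed genes by a per-animal fold-change voting rule; and detects
    genes whose two splice forms reverse expression dominance after
    exercise. A fully parameterised synthetic-data generator emulates the
    24-sample study design with planted effects, genotypes, junction
    artifacts and isoform switches so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
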