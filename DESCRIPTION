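Package: snpprio
Title: Gene-Centric SNP Prioritization with Learned Feature Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes single nucleotide polymorphisms (SNPs) around a set of
    candidate genes by combining per-SNP biomolecular feature annotations
    (localization class, epigenetic tracks, protein-level evidence and more)
    into a weighted linear score. Default feature weights are learned from
    disease benchmarks with a genetic algorithm that maximizes sensitivity
    under a relative score threshold and a filtering-ratio constraint,
    assessed by leave-one-out cross-validation over an (epsilon, Tr) grid.
    Input gene sets can be expanded through ontology-based semantic similarity
    (Wang and relevance measures), and top-ranked SNPs can be tested for
    pathway, ontology-term or disorder enrichment with hypergeometric tests
    and Benjamini-Hochberg false discovery rate control. A seeded synthetic
    data generator emulates the annotation warehouse and disease benchmarks so
    the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
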