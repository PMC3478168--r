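Package: orthodiv
Title: Comparative Transcriptome Divergence Between Closely Related Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing the transcriptomes of
    closely related species from assembled transcript sets: reciprocal
    best-hit orthology with paralog filtering against a reference protein
    database, rule-based CDS/UTR delineation from protein hits, sequence
    divergence partitioned by site class (nondegenerate, fourfold
    degenerate, CpG and non-CpG) with transition/transversion summaries,
    Nei-Gojobori Ka/Ks estimation with Fisher exact tests, Markov-cluster
    protein families with hypergeometric term enrichment, neighbor-joining
    phylogeny from concatenated ortholog alignments, RPKM expression
    quantification, and pileup-based SNP detection with synonymous/
    nonsynonymous classification.  A bundled sequence-evolution simulator
    generates ortholog triples, paralogs, reads and annotation tables with
    known ground truth so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
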