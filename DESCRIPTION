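Package: splicepotts
Title: Sparse Maximum-Entropy Potts Models of 5' Splice-Site Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits regularized maximum-entropy (Potts) models with fields and
    L1-sparse pairwise couplings to ensembles of 9-nucleotide 5' splice-site
    (donor) sequences, by exact enumeration of the 4^9 state space. Provides
    donor-site extraction from genome FASTA plus GTF/GFF3 annotation,
    one- and two-site marginal estimation, data-driven energy scoring with
    random and genomic GT-locus decoy nulls, summaries of coupling patterns
    between consensus and non-consensus site-base combinations, Sankoff
    parsimony and Maddison-Slatkin randomization tests for phylogenetic
    signal in coupling presence/absence, dendrogram construction from model
    two-site probabilities with cophenetic, Fowlkes-Mallows and entanglement
    comparisons, and synthetic-data generators (planted Potts models, toy
    genomes, multi-species panels, traits on trees) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings,
    rtracklayer,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
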