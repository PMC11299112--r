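Package: orfancestry
Title: Dating the Origin of Short ORFs by Ancestral Sequence Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the phylogenetic branch of origin of short protein-coding
    ORFs from nucleotide multiple sequence alignments of orthologous loci.
    Reconstructs ancestral sequences at internal tree nodes by marginal
    maximum likelihood under a GTR model (Felsenstein pruning) with
    parsimony-based indel reconstruction, scans ancestors for open reading
    frames under ATG and STOP-STOP definitions, scores each ancestral ORF
    against the extant focal ORF with the reading frame conservation (RFC)
    measure on a global pairwise alignment, attaches a composition-preserving
    randomization P-value to each ancestor, and assigns a branch of origin
    with ensemble confidence classification across methodological variants.
    Includes a tree-based sequence evolution simulator (substitutions and
    indels, optional planted ORFs) that provides ground truth for end-to-end
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
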