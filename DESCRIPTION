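Package: rhizocontinuum
Title: Genomic Clusters and the Continuum of Divergence in Rhizobial Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A comparative-genomics workflow for bacterial genome collections of
    the kind assembled for rhizobia: pairwise average nucleotide identity (ANI)
    and genome coverage with threshold-based genomic-cluster calling, core-genome
    marker phylogenetics with congruence-based marker filtering, consensus
    (bidirectional-best-hit intersected with Markov-clustering) pangenome
    construction and rarefaction, symbiotic-gene and Rep-protein family
    profiling, and chromosome-versus-symbiotic-plasmid synonymous-substitution
    contrasts for detecting recent plasmid transfer. Includes a genome-evolution
    simulator (clonal species tree, JC69 divergence, accessory gene gain/loss,
    wholesale symbiotic-plasmid transfer) that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phangorn
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
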