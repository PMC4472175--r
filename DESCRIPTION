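Package: csphylo
Title: Consensus-Site Phylogenomics from Cross-Species RNA-Seq Read Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly-free, reference-guided construction of codon-partitioned
    phylogenetic supermatrices from RNA-Seq reads of non-model species. Reads
    are placed on a paralog-collapsed reference CDS set by a translated
    (protein-space) seeded mapper whose score cutoff is calibrated against a
    hexamer-preserving shuffled decoy so that the mapping false discovery rate
    stays below a chosen bound. Covered reference sites are classified as
    consensus (CS), ambiguous (AS) or uncovered (UNS); consensus codons shared
    by all samples are concatenated into a supermatrix with codon-position
    partitions and exported in PHYLIP, FASTA and NEXUS formats. Additional
    components detect allele-of-origin at lineage marker sites (hybrid
    screening), check cross-library consistency of consensus calls, and
    provide neighbor-joining and Robinson-Foulds utilities for topology smoke
    tests. A simulator generates reference CDS sets, sequences evolved along a
    known tree, sequencing reads, hybrids and paralog families with recorded
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    igraph,
    data.table,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
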