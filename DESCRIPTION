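Package: dyadMeth
Title: Dyad-Resolution DNA Methylation Analysis for Hairpin Bisulfite Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dyad-resolution DNA methylation analysis from hairpin
    bisulfite sequencing (hpBS-seq) call tables. Identifies symmetric cytosine
    dyads (CG, CWG, CWWG, CCG/CSG) in a genome, pairs per-strand calls into
    per-molecule dyad statuses, estimates bisulfite conversion rates from a
    spike-in, performs in silico strand annealing (iSA) of unlinked fragments,
    aggregates dyads into genomic bins, compares observed full-methylation to a
    stochastic per-cytosine null (Exp/Theo ratio), fits saturation and linear
    maintenance-efficiency models stratified by H3K9me2, calls differentially
    methylated regions with group classification and CSG content, quantifies
    strand concordance of neighbouring hemi-methylated dyads and conditional
    correlations among CSG cytosines, and builds nucleosome-centred
    methylation, occupancy and sequence-context profiles. Ships a synthetic
    methylome generator emulating replication-coupled maintenance methylation
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, Sequencing, Software
RoxygenNote: 7.3.3
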