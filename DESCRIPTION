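Package: rivervirome
Title: Desk-Scale Viral Metagenomics of River Water Communities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained viral metagenomics workbench for multi-library
    river-water virome surveys. Simulates mock viral communities with known
    ground truth (six sampling-site libraries plus a blank control), cleans
    raw reads (window-based deduplication, Phred tail trimming, adapter
    masking), assembles them per library with a greedy overlap-layout-
    consensus assembler, classifies contigs and singlet reads by translated
    seed-and-extend homology search with Karlin-Altschul E-values against a
    viral protein database with competitive filtering against a non-virus
    database and profile-HMM rescue of remote homologs, builds family- and
    species-level community profiles, and compares communities by analytic
    rarefaction, Bray-Curtis dissimilarity, principal coordinates analysis,
    UPGMA clustering and the Friedman rank-sum test. Viral contigs are
    extended and merged, open reading frames predicted and annotated, and
    hallmark genes (TerL, MCP, NS1, Rep, RdRp) extracted for gap-masked
    alignment and neighbor-joining phylogenies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    vegan,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap
Config/testthat/edition: 3
NeedsCompilation: yes
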