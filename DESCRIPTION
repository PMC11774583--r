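Package: codivscan
Title: Phylogeny-Wide Tests of Host-Microbe Co-Diversification Versus
    Geography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans a strain-level bacterial phylogeny for clades whose
    diversification parallels either the host phylogeny (partner fidelity)
    or the geography of the host populations (isolation by distance). Each
    clade in the distal tenth of the tree is tested by Mantel permutation
    test against host patristic distances and great-circle distances
    between sampling sites, with Benjamini-Hochberg correction and
    classification from the two correlations and their difference.
    Includes host-fidelity tests for strains from sympatric heterogeneric
    hosts, branch-length-weighted taxon summaries with sign tests,
    weighted Welch t-tests and simulation-based phylogenetic ANOVA, and a
    synthetic cophylogeny generator with ground-truth regime labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
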