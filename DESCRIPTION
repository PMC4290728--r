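Package: metaclust
Title: Ensemble Consensus Clustering of Metagenomic Sample Similarity
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects microbial community patterns among metagenomic samples
    by ensemble consensus clustering. Pairwise sample similarity is scored
    on a shared phylogenetic tree by propagating common taxon abundance
    towards the root with a branch-length decay; a generation phase runs
    four families of base clusterers (EM Gaussian mixture, k-means,
    average-linkage hierarchical, density-based) over a parameter grid on
    the similarity network and summarises them in a consensus co-clustering
    matrix; an identification phase factorises the consensus matrix by
    symmetric nonnegative matrix factorisation under a Kullback-Leibler
    cost with L1 sparsity and thresholds the soft memberships into possibly
    overlapping clusters. Includes evaluation against meta-class reference
    clusters (f-measure, pair-based PR, F-score), habitat/gender composition
    and gender-variation summaries, and synthetic generators with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    mclust,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
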