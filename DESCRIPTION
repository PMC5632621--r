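Package: nichedelim
Title: Niche Comparisons, Discrete Character Evolution and Haplotype
    Networks for Integrative Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting closely related lineages by combining
    ecological and molecular evidence. Quantifies climatic niches of
    georeferenced lineages in a kernel-smoothed two-axis environmental
    ordination calibrated on the whole background (PCA-env), and compares
    them with Schoener's D overlap, Levins' niche breadth, and
    randomization tests of niche equivalency and similarity. Reconstructs
    ancestral states of discrete morphological characters on fixed trees
    under the one-parameter Markov k-state (Mk) model by maximum
    likelihood. Codes alignment gaps as binary characters by simple indel
    coding and builds statistical-parsimony haplotype networks with
    hypothetical intermediate haplotypes. A seed-deterministic synthetic
    data generator produces occurrence sets on spatially autocorrelated
    environmental rasters, Mk-evolved characters and toy alignments with
    known ground truth, so every stage of the workflow is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
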