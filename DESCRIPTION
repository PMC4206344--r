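Package: phylocover
Title: Phylogenetic Diversity Coverage of Site-Based Conservation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether a network of conservation sites selected
    for threatened species captures above-average taxonomic and phylogenetic
    diversity. Computes per-grid-cell diversity profiles (species richness,
    red-list richness, Faith's phylogenetic diversity and mean pairwise
    phylogenetic distance) from presence/absence rasters and a rooted
    phylogeny, runs a tip-shuffle null for the branch length spanned by
    threatened species, measures site-network effectiveness against uniform
    random cell draws in per-cell-average and complementarity ('total')
    modes, maps top-decile diversity hotspots, and generates fully synthetic
    study scenarios (Yule trees, spreading-dye species ranges on a gridded
    landscape with a richness gradient, seasonal range shifts, flagged taxa
    and focal sites) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    optparse
Config/testthat/edition: 3
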