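Package: morphogap
Title: Detecting and Tracking Morphological Gaps in Trait Space with
    Persistent Homology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects unoccupied regions ("gaps") of a morphological trait
    space and tracks them through evolutionary time. Builds a PCA
    morphospace from species trait tables, reconstructs ancestral states
    on a dated phylogeny under Brownian motion by generalised least
    squares, interpolates lineage trait values at regular time slices,
    identifies loop-like gaps in each slice with Vietoris-Rips persistent
    homology (implemented here with representative cycles over GF(2)),
    characterises each gap by persistence, centroid, size and sparsity,
    links gaps across slices into gap series, and compares empirical gaps
    against Brownian-motion null simulations on the same tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    phytools,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
VignetteBuilder: knitr
Config/testthat/edition: 3
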