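Package: dynloop
Title: Expression-Dependent Dynamic Loop Simulation of Interphase Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained lattice Monte-Carlo simulation of interphase
    chromosomes under the Dynamic Loop model, in which spatially proximal
    monomers form transient chromatin loops with probabilities derived from
    gene-expression profiles. Provides expression-profile ingestion and
    binning (150 kb per monomer), affinity mapping, a self-avoiding-walk
    engine with excluded volume and Poisson-lifetime loop bonds, two-phase
    equilibration with autocorrelation-based conformation sampling, and the
    full observable suite used to characterise chromosome territories:
    mean-square spatial distances, loop-size distributions and exponents,
    local density by 3-D Gaussian kernel density estimation, volume ratios,
    gyration-tensor asphericity, radial territory positioning, monomer
    mobility (MSMD), and lattice-to-physical scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
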