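Package: dynloop
Title: Dynamic Loop Model of Mitotic Chromosome Condensation and Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lattice Monte Carlo simulator for a coarse-grained chromatin
    fibre that condenses into a mitotic-chromatid-like rod through
    transient, probabilistic self-cross-linking (dynamic loops).  The chain
    is a Bond Fluctuation Model polymer with excluded volume; cross-links
    form stochastically between fibre segments that diffuse into bonding
    range within a genomic cutoff and dissolve after Poisson-distributed
    lifetimes.  The package also provides the analysis machinery for such
    simulations: integrated autocorrelation times with Sokal windowing,
    coarse-grained and smooth backbone extraction, directional correlation
    and persistence length, radial monomer density and thickness,
    lengthwise compaction ratios, and equilibrium force-extension
    (stretching) experiments with elastic moduli and Poisson's ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
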