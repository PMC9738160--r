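Package: elastochain
Title: Freely-Jointed-Chain Elasticity Analysis of Spidroin Peptide Fragments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the elastomeric behaviour of polyglycine-rich spider-silk
    (spidroin) peptide fragments as a freely jointed chain (FJC). Provides the
    Langevin function and a high-accuracy numerical inverse, the FJC
    force-extension law, exact Monte-Carlo sampling of chain conformations
    under constant end force, an overdamped bead-spring Brownian-dynamics
    pulling simulator, trajectory statistics (end-to-end distance, Kabsch
    RMSD, equilibration detection), and weighted least-squares fitting of the
    FJC link length to force-extension curves via the fjc_fit() modelling
    interface. Derived elastomer quantities (contour length, equilibrium
    end-to-end distance, hidden length) are reported per fragment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
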