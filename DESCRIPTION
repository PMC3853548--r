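Package: treesum
Title: Summary Trees from Posterior Samples of Time Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Condenses a posterior sample of rooted ultrametric (time) trees
    into a single summary tree. Implements four rooted tree scores (rooted
    branch score, its squared variant, the heights score and the rooted
    agreement score), topology selectors (maximum clade credibility,
    conditional clade distribution, total clade branch, highest posterior
    frequency), height-assignment constructions (per-clade mean/median,
    common-ancestor heights, majority-rule consensus), optimization-based
    minimum-distance summary trees with an analytic gradient, and the
    taxa-partition summary tree. Includes Kingman coalescent and
    Jukes-Cantor simulators, model-fit likelihoods, summary-vs-truth error
    measures and a bootstrap ranking protocol for comparing methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
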