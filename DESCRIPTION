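Package: opsmc
Title: Online Phylogenetic Inference by Sequential Monte Carlo with Guided
    Attachment Proposals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Updates a Bayesian posterior sample of unrooted phylogenetic
    trees with newly arriving aligned sequences using sequential Monte Carlo
    (SMC). Each new taxon is grafted onto every particle tree by a three-step
    attachment proposal (attachment branch, attachment position, pendant
    branch length); the proposal steps range from draws against the prior to
    guided variants that use Fitch parsimony, the Jukes-Cantor likelihood, and
    a four-parameter surrogate of the single-branch log-likelihood curve.
    Includes a Felsenstein-pruning likelihood engine with analytic branch
    derivatives, stratified resampling, a reference Metropolis-Hastings
    sampler for producing and validating posterior tree samples, split-based
    convergence diagnostics (ASDSF, split-frequency differences, weighted
    Robinson-Foulds), and a birth-death/JC69 benchmark simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
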