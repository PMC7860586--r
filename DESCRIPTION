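Package: rpcsim
Title: Simulation and Prediction of the Purebred-Crossbred Genetic Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of selected purebred breeding lines and
    computation of the genetic correlation between purebred and crossbred
    performance (r_pc) at the causal-locus level. Provides functional trait
    architectures with dominance and pairwise epistasis, an average-excess
    engine that yields average effects of allele substitution for purebred and
    crossbred performance in two-, three- and four-way crosses, and closed-form
    predictors of r_pc from parental-line variance components, together with
    the experiment grid used to validate those predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
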