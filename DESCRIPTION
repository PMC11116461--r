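Package: lehstress
Title: Ontogenetic Modelling of Dental Enamel Hypoplasia in Paleolithic Hominins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing linear enamel hypoplasia (LEH) and other
    enamel growth disruptions in Neanderthal and Upper Paleolithic modern
    human dentitions. Provides tooth-specimen and defect-observation data
    structures with delimited-file input/output and preservation-based
    inclusion filtering; a deterministic eleven-stage crown-formation
    staging system with matched systemic-stress-episode detection; two
    Bayesian hierarchical Bernoulli models (tooth-level defect presence by
    taxon and tooth type, and individual-level stress-episode occurrence
    across developmental stages via per-taxon penalized splines) fitted
    with a built-in no-U-turn sampler; posterior summaries, marginal cell
    probabilities, odds-ratio contrasts, finite-difference derivative
    change-period detection, convergence diagnostics and posterior
    predictive checks; and a seeded synthetic cohort generator with known
    ground truth for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
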