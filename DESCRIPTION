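Package: phorescreen
Title: Ligand-Based Pharmacophore Modeling and Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative three-dimensional pharmacophore modeling from
    activity-annotated ligands and pharmacophore-based virtual screening.
    Provides feature perception (hydrogen-bond donors and acceptors,
    hydrophobes, aromatic rings), weighted rigid superposition and fit-value
    scoring against toleranced feature spheres, HypoGen-style hypothesis
    generation with an error/weight/configuration cost model and simulated
    annealing, statistical validation by Fischer randomization, test-set
    prediction and Guner-Henry enrichment scoring, a Lipinski rule-of-five
    screening funnel, consensus aggregation of external docking score
    matrices, and fully seeded synthetic benchmark generators for planted
    pharmacophore recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
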