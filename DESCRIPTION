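Package: gcClonality
Title: Clonal Dynamics of Single Germinal Centers from Multicolor Lineage Tracing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of longitudinal single-germinal-center
    imaging data from Confetti multicolor lineage tracing. Provides the
    10-state Confetti color model and its stochastic recombination
    distribution, per-germinal-center clonality statistics (clonal dominance,
    top-two dominance, clonal divergence score, meander index), detection of
    clonal inversion events, exponential fits of early seeding trajectories
    with doubling times and confidence intervals, fidelity regression between
    paired in vivo and ex vivo measurements, and PCA-based testing of
    inter-germinal-center synchrony within mice. Includes a Wright-Fisher
    style simulator of labeled germinal center clonal dynamics with selection,
    mutation, optional inter-germinal-center reentry coupling, and the
    multinomial observation model of manual cell counting, so every analysis
    stage can be exercised on synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, SingleCell, Immunology, TimeCourse, Clonality
Config/testthat/edition: 3
RoxygenNote: 7.3.3
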