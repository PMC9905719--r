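Package: aquassess
Title: Surface Water Quality Assessment with Weighted Grey Relational
    Feature Selection and PSO-Tuned Multiclass SVM
Version: 0.1.0
Authors@R:
    person("A.", "Rivers", email = "a.rivers@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing river water quality from routine monitoring
    records. Indicators are ranked and selected with a grey relational
    analysis whose relational degrees are weighted by combined subjective
    (analytic hierarchy process) and objective (CRITIC) indicator weights.
    Samples are then classified into the six GB3838-2002 surface-water
    quality categories by a one-vs-one multiclass support vector machine
    whose kernel hyperparameters are tuned with a particle swarm optimizer
    using a linearly decreasing inertia weight. Includes a synthetic data
    generator emulating the class-band structure of the national standard,
    evaluation metrics (accuracy, macro precision/recall, RMSE on the
    ordinal class encoding), and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
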