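Package: FluxPerturb
Title: Context-Specific Metabolic Models and Perturbation-Based Drug
    Target Ranking
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based metabolic modeling toolkit for immune-cell
    drug-target discovery. Integrates binary multi-omics activity calls,
    extracts context-specific models from a template genome-scale network
    (GIMME), simulates single-gene knockouts by gene-protein-reaction
    logic with MoMA flux prediction, classifies flux changes against
    disease differential-expression signatures, and ranks candidate
    targets by a perturbation effect score aggregated across cell-type
    models. Ships a synthetic-data generator producing toy networks and
    omics inputs with planted ground truth so the full pipeline runs and
    validates offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'fba.R'
    'gimme.R'
    'gpr.R'
    'hygiene.R'
    'knockout.R'
    'model-io.R'
    'moma.R'
    'omics.R'
    'pipeline.R'
    'scoring.R'
    'solver-engine.R'
    'synthetic.R'
    'validation.R'
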