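Package: isoshift
Title: Isothermal Shift Assay Analysis and Thermal Proteome Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects ligand-induced protein thermal-stability shifts from
    single-temperature (isothermal shift assay, iTSA) TMT proteomics
    experiments. Provides a closed-form sigmoid melting model, a
    ground-truthed simulator of isothermal and thermal-gradient (TPP-style)
    reporter-ion experiments in the MaxQuant proteinGroups dialect, a
    moderated empirical-Bayes two-sample testing pipeline with
    quantile normalization and Benjamini-Hochberg correction, melting-curve
    fitting with quality-control filters and a melting-temperature library,
    a replicate-subsampling power analysis, and head-to-head benchmarking of
    the isothermal versus gradient experimental designs against simulated
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    knitr
biocViews: Proteomics, MassSpectrometry, Software, StatisticalMethod,
    DifferentialExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
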