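Package: DGGEtools
Title: Denaturing Gradient Gel Electrophoresis Fingerprint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of denaturing gradient gel electrophoresis (DGGE)
    community fingerprints: lane detection and densitometric profile
    extraction from gel images, morphological background subtraction,
    prominence-based band calling with cross-lane band-class matching,
    Jaccard and Pearson similarity matrices, UPGMA dendrograms with Newick
    export, and community-ecology statistics (band-count richness,
    Pareto-Lorenz / Gini community organization, moving-window percent
    change and rate of change). Includes a synthetic gel simulator that
    renders ground-truth community trajectories to gel images so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'image-processing.R'
    'band-calling.R'
    'fingerprint-stats.R'
    'clustering.R'
    'ecology-dynamics.R'
    'pipeline.R'
    'synthetic-data.R'
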