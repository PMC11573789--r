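Package: RatioScreen
Title: Ratiometric Analysis of Split-Luciferase Interactome Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative protein-fragment complementation
    (split-luciferase, NanoBiT-style) interactome screens in arrayed
    microtiter plates. Implements the full analysis path from raw plate
    luminescence and cell-density readings to normalized log2 signals
    (background subtraction, density correction, per-plate regression
    against cross-replicate medians), ratiometric interaction scores with
    replicate-level significance, benchmarking against literature-curated
    reference interactions (confusion counts, sensitivity, precision,
    specificity, Matthews correlation coefficient, ROC and precision-recall
    curves), evidence curation with ontology-aware deduplication, and
    mutant-versus-wild-type differential interaction profiling with
    hierarchical clustering. A synthetic plate-screen generator reproduces
    the statistical structure of such screens (log-normal protein
    abundances, abundance- and colocalization-dependent fragment
    self-association background, plate effects, detection-limit censoring)
    so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
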