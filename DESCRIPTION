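Package: ednacomp
Title: Multi-Marker eDNA and Traditional Biodiversity Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing biodiversity structure measured by
    environmental DNA (eDNA) metabarcoding markers and by traditional field
    surveys over the same sampling plots. Implements Jost's multiplicative
    Hill-number diversity partitioning (alpha, beta, gamma, turnover),
    read-subsampling rarefaction, Mantel and Procrustes (PROTEST)
    permutation tests, second-stage MDS of method correlations,
    distance-decay regression against elevation, greedy
    complementarity-based plot prioritization, stepwise variance-inflation
    screening of environmental covariates, and distance-based redundancy
    analysis with permutation model selection. A synthetic
    gradient-metacommunity generator reproduces the statistical structure
    these analyses assume (elevational niches, multi-marker scale
    differences, plot/subplot hierarchy, collinear covariates) so the whole
    pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
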