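Package: mqtlr
Title: Meta-QTL Analysis for Multi-Population Genetic Mapping Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for consolidating quantitative trait loci (QTL) reported
    across independent bi-parental mapping populations into meta-QTL (MQTL).
    Covers curation of published QTL tables with estimation of missing effect
    statistics, construction of a consensus genetic map around a fixed
    reference with anchor-based linear projection of QTL peaks and confidence
    intervals, per-chromosome consolidation by a one-dimensional Gaussian
    mixture with known per-QTL positional variances and model selection by a
    vote over five information criteria (AIC, AICc, AIC3, BIC, AWE),
    genome-distribution and centromere-anchored density summaries, binary
    trait-incidence co-localization statistics, physical anchoring of MQTL
    intervals for comparison with genome-wide association signals, and
    cross-species orthologous MQTL detection through shared ortholog pairs.
    Includes a seeded synthetic-study generator with known ground truth for
    end-to-end validation, and fixtures transcribing a published catalog of
    100 wheat MQTLs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
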