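Package: riailmap
Title: Linkage Mapping, eQTL Hotspot Detection, and Causal Mediation for
    Two-Parent Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics analysis chain for two-parent recombinant
    inbred advanced intercross line (RIAIL) panels, as used in Caenorhabditis
    elegans drug-response studies. Provides marker-regression genome scans with
    the closed-form LOD statistic -n*ln(1-R^2)/(2*ln 10), permutation-based
    genome-wide significance thresholds, iterative forward search with
    marker cofactors, QTL annotation (1.5-LOD-drop confidence intervals,
    variance explained, allelic effects), panel-scale expression QTL mapping
    with a permutation false-discovery-rate threshold, local/distant eQTL
    classification, Poisson bin-enrichment eQTL hotspot detection, and
    bootstrap causal mediation analysis that ranks candidate mediator probes.
    A synthetic-data module simulates RIAIL genotype mosaics (Haldane model
    with map expansion), quantitative traits with planted QTL, expression
    panels with local/distant eQTL and a regulatory hotspot, and mediated
    drug traits, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
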