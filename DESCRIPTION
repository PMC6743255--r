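Package: sbmnet
Title: Stochastic Block Model Analysis of Correlation-Based Biomolecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Spearman correlation networks from entity-by-sample omics
    abundance matrices, reduces them to simple binary graphs by significance of
    correlation or by a scale-free degree-distribution criterion, fits four
    microcanonical stochastic block model variants (classical, degree-corrected,
    hierarchical, degree-corrected hierarchical) by minimum description length,
    selects among them by posterior odds, scores putatively missing and spurious
    edges by description-length differences at the fixed best partition, and
    characterizes blocks by hypergeometric term overrepresentation with
    hierarchy-aware distance summaries. Includes generators for graphs with
    planted block structure, expression matrices with planted co-expression
    modules, and synthetic annotation hierarchies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
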