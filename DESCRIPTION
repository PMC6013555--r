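Package: npscreen
Title: Screening Neuropsychiatric-Disorder Gene Sets in Brain Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening bipolar-disorder, schizophrenia and major
    depressive disorder associated gene sets in probe-level brain expression
    data from a mouse model of Alzheimer's disease. Builds per-disorder gene
    pools from Gene Ontology annotations (GAF/OBO parsing, qualifier and
    taxon filtering, is_a descendant expansion), calls differentially
    expressed genes per brain region and age with a joint p-value and
    fold-change criterion, computes per-term and per-disorder summary
    statistics and rankings, classifies cross-age expression behaviour
    (consistent, contra-regulated, region-specific), and ships a synthetic
    data generator with planted effects so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
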