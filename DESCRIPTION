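Package: gotissue
Title: Tissue-Specific Gene Ontology Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Offline Gene Ontology (GO) over-representation analysis against a
    tissue-restricted gene background. Parses OBO ontology and GAF annotation
    files, selects the genes expressed in a chosen tissue from a GTEx-style
    expression matrix using dual TPM and read-count prevalence thresholds,
    tests a user gene list for enriched GO terms with an upper-tail
    hypergeometric test and Benjamini-Hochberg FDR control, and writes result
    tables (TSV, HTML), GO-lineage graphs (Graphviz DOT) and pairwise
    comparisons of enrichment runs. Includes a synthetic-fixture generator
    that plants known enrichment signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
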