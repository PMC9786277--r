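Package: gwas2drug
Title: Genomic Network Analysis for Drug Repurposing from GWAS Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated genomic-network drug-repurposing pipeline for
    acute lymphoblastic leukemia (ALL) and similar GWAS-driven studies:
    association-table filtering by p-value and odds ratio, linkage
    disequilibrium proxy expansion, six-criterion functional-annotation
    gene scoring (missense, cis-eQTL, three Gene Ontology namespaces, and
    KEGG enrichment via the EASE statistic), risk-gene classification,
    confidence-weighted protein-interaction network expansion with a fixed
    interactor budget, druggability overlap against a drug-target table,
    and connectivity-score ranking of candidate drugs against a comparator.
    A synthetic-data generator plants recoverable ground truth in every
    input dialect so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    fgsea
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
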