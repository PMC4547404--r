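Package: hubprior
Title: Disease-Gene Prioritization from Protein Interaction Networks and
    Differential Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by integrating an
    evidence-filtered protein-protein interaction network with two-group
    (disease versus control) expression data.  Differentially expressed genes
    are selected with a regularized t statistic and permutation-based false
    discovery rate, hubs are detected from degree and betweenness centrality
    of the disease-specific network, and hubs are scored two ways: by the
    disease-minus-control difference in average hub-interactor Pearson
    correlation (assessed by a label-permutation test with Bonferroni
    correction) and by the median Wang semantic similarity between a hub and
    its interactors on the Gene Ontology biological-process hierarchy.  The
    combined list is evaluated by reference-set overlap, tissue-specificity
    filtering, hypergeometric GO over-representation, and leave-one-out
    cross-validated random-forest classification of sample outcome from
    per-sample co-expression-difference features.  A synthetic fixture
    generator provides statistically controlled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
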