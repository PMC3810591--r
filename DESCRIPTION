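Package: seednet
Title: Seed-Gene Sub-Network Inference from Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers disease-relevant sub-networks from lists of
    differentially expressed "seed" genes mapped onto background
    interaction or co-expression networks. Seed pairs within shortest-path
    distance two are connected through their intermediate genes and the
    induced sub-network is mined for hub seed genes and their ego-network
    modules. Gene-set over-representation is assessed with a one-sided
    Fisher exact test and its conservative EASE-score variant with
    Benjamini-Hochberg false discovery rate control, and microRNAs
    regulating sub-network genes are ranked by hypergeometric target
    enrichment on a miRNA-gene bipartite graph. A synthetic-data generator
    produces backgrounds, seed sets with planted clusters, gene sets with
    a planted enriched term and miRNA target maps with a planted enriched
    miRNA so the full pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
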