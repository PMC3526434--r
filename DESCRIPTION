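Package: argstr
Title: Genome-Wide ARG-Based Population Classification from Multi-Allelic STR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral recombination graph (ARG) estimates from
    sparse, multi-allelic short tandem repeat (STR) genotype panels and uses
    them to classify samples into populations. Chromosomes are staged either
    separately (solo method) or concatenated after random circular ordering,
    flipping and cutting (ensemble method); a pattern-based recombination
    detector with multi-setting consensus yields a recomatrix from which a
    subARG is built, node ages are estimated from carrier counts over
    non-mixing segments, and pairwise MRCA-age distances are consolidated
    across randomized iterations. The consolidated matrix is summarized as a
    neighbor-joining classification tree, k-cluster partitions and an MDS
    embedding, and evaluated against a reference partition via contingency
    tables, diagonal-maximizing label assignment, precision/recall/F-index,
    the partition metric and an agreement index. A coalescent STR panel
    simulator with stepwise mutation provides ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
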