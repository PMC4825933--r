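Package: archexpr
Title: Pathway-Regulated Gene Classification for FACS-Purified Pharyngeal
    Arch Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives Edn1- and Notch-regulated gene sets from RPKM expression
    matrices of FACS-purified zebrafish pharyngeal-arch neural crest cells.
    Implements the two-step arch-enrichment filter (minimum-expression floor
    plus double-positive over single-positive enrichment ratios), fold-change
    ratio classification of genes as pathway-activated or -inhibited from
    paired gain- and loss-of-function contrasts, refinement of the Notch lists
    against a gamma-secretase-inhibitor (DBZ) contrast, gene-set intersections
    and top-k regulated lists. Downstream statistics cover temporal
    fold-change distributions of gene lists (Kruskal-Wallis, pairwise
    Mann-Whitney with exact enumeration under ties, Bonferroni correction) and
    genotype-phenotype penetrance contingency tests. A synthetic-data
    generator emulates the full experimental design with planted, labelled
    gene classes so every stage is verifiable by recovery of the planted
    labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
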