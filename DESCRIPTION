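Package: vinherit
Title: Microbial Inheritance Analysis for Clonally Propagated Vines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for detecting microbial inheritance
    between clonally propagated mother plants and their progeny in
    multi-site field designs. Implements community-structure analysis
    (Bray-Curtis PCoA, PERMANOVA, an alpha-diversity panel with
    generation contrasts, and LEfSe-style biomarker effect sizes),
    a quartile-based mother-daughter pair-clustering statistic with
    per-site proportions, and assembly-process metrics (beta-MNTD /
    beta-NTI against tip-shuffle nulls and a per-family normalized
    stochasticity ratio) tested with mother-daughter assignment
    permutation nulls. Ships a lineage-structured synthetic-community
    generator with tunable vertical-transmission fraction and
    phylogenetically correlated environmental filtering so every stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    permute,
    ape,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
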