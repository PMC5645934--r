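Package: gutshift
Title: Multifactor Analysis of Gut Metagenomes in Alcohol-Related Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical pipeline for shotgun-metagenomic studies that
    disentangle the effects of alcohol dependence and alcoholic liver
    cirrhosis on the gut microbiota. Provides gene-length normalization of
    read counts to relative abundances, aggregation to taxa and KEGG
    orthology groups, alpha diversity and Bray-Curtis ordination,
    dendrogram-based outlier detection, Mann-Whitney differential abundance
    with Benjamini-Hochberg control, a rank-based test for enrichment of
    oral (buccal) species, PERMANOVA screening and multifactor linear
    association modelling, virulence-factor gene quantification from
    homology hits, and a synthetic cohort generator with a planted-effect
    truth registry for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
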