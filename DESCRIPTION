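Package: rumenstab
Title: Temporal Stability and Host-Phenotype Association Analysis of the
    Rumen Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for repeated-measures 16S rRNA amplicon
    surveys of the dairy-cow rumen. Classifies per-OTU temporal stability
    across two sampling events with Lin's concordance correlation
    coefficient, screens each OTU against milk and methane phenotypes with
    a per-feature linear mixed model under Bonferroni control, compares
    taxon abundances across lactation stages (Tukey HSD), computes alpha
    diversity and Bacteroidetes/Firmicutes trends, estimates a SparCC
    compositional co-occurrence network with permutation p-values, and
    ranks keystone genera by betweenness centrality. Includes a synthetic
    two-visit cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    withr
Suggests:
    lme4,
    lmerTest,
    vegan,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
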