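#!/usr/bin/env Rscript
# Per-OTU mixed-model screen of milk phenotypes, overall and by parity
# stratum, with Bonferroni control over the full OTU table.
suppressPackageStartupMessages(library(rumenstab))

rar <- read_otu_table("data/cohort/otu_counts_rarefied.tsv",
                      "data/cohort/otu_taxonomy_rarefied.tsv")
md <- read_sample_metadata("data/cohort/metadata.csv")
ph <- read_phenotypes("data/cohort/phenotypes.csv")

dir.create("results", showWarnings = FALSE)
for (coh in c("all", "multiparous", "primiparous")) {
  res <- screen_all(rar, md, ph, c("fat_pct", "protein_pct"), cohort = coh)
  write.table(res, sprintf("results/screen_%s.tsv", coh), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bon <- attr(res, "bonferroni")
  cat(sprintf("%s: %d significant at p < %.3g (baseline -log10 p = %.2f)\n",
              coh, sum(res$significant), bon$threshold, bon$neg_log10))
}
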