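#!/usr/bin/env Rscript
# Composition over lactation: phylum abundance by stage (Tukey HSD), alpha
# diversity with paired tests between visits, and B/F-ratio trends on DIM.
suppressPackageStartupMessages(library(rumenstab))

rar <- read_otu_table("data/cohort/otu_counts_rarefied.tsv",
                      "data/cohort/otu_taxonomy_rarefied.tsv")
md <- read_sample_metadata("data/cohort/metadata.csv")
md <- md[match(rar$sample_ids, md$sample_id), ]

dir.create("results", showWarnings = FALSE)

phylum <- collapse_taxonomy(rar, "phylum")
tk <- tukey_stage_comparison(relative_abundance(phylum), md$stage)
write.table(tk, "results/tukey_stage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

adiv <- alpha_diversity(rar)
write.table(adiv, "results/alpha_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
paired <- do.call(rbind, lapply(c("multiparous", "primiparous"), function(coh) {
  sub <- md[md$parity_class == coh, ]
  pr <- pair_samples(rar, sub)
  do.call(rbind, lapply(c("chao1", "observed_species"), function(metric) {
    a1 <- adiv[[metric]][match(colnames(pr$x1), adiv$sample_id)]
    a2 <- adiv[[metric]][match(colnames(pr$x2), adiv$sample_id)]
    tt <- paired_ttest(a1, a2)
    data.frame(cohort = coh, metric = metric, t = tt$t, p_value = tt$p_value,
               mean_difference = tt$mean_difference, df = tt$df)
  }))
}))
write.table(paired, "results/alpha_paired_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

bf <- merge(bf_ratio(rar), md, by = "sample_id")
trends <- do.call(rbind, lapply(unique(bf$parity_class), function(coh) {
  sub <- bf[bf$parity_class == coh, ]
  bf_trend(sub$bf_ratio, sub$dim, coh)
}))
write.table(trends, "results/bf_trends.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(trends)
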