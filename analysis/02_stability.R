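#!/usr/bin/env Rscript
# Per-OTU temporal stability between the two sampling events (Lin's
# concordance + Pearson p), with the histogram and stable-genus summary.
suppressPackageStartupMessages(library(rumenstab))

rar <- read_otu_table("data/cohort/otu_counts_rarefied.tsv",
                      "data/cohort/otu_taxonomy_rarefied.tsv")
md <- read_sample_metadata("data/cohort/metadata.csv")

stab <- assess_stability(rar, md)
summ <- stability_summary(stab)

dir.create("results", showWarnings = FALSE)
write.table(stab, "results/stability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ$histogram, "results/stability_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(genus = names(summ$stable_taxonomy),
                       n_stable = as.integer(summ$stable_taxonomy)),
            "results/stable_genera.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("stable OTUs: %d / %d (%.1f%%)\n", summ$n_stable, nrow(stab),
            100 * summ$stable_fraction))
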