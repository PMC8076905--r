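#!/usr/bin/env Rscript
# Simulate the two-visit cohort and rarefy it; all later steps read data/.
suppressPackageStartupMessages(library(rumenstab))

seed <- 42L
# 60 cows x 2 visits, 1000 OTUs, 5% designed stable; a handful of OTUs are
# given true phenotype effects so the screen has known positives to find
cfg <- sim_config(seed = seed,
                  causal_otus = data.frame(
                    otu = c(17, 204, 561, 88, 902),
                    phenotype = c("fat_pct", "fat_pct", "fat_pct",
                                  "protein_pct", "protein_pct"),
                    effect = c(1.5, 1.5, 1.5, 1.2, 1.2)))
sim <- simulate_cohort(cfg)
write_cohort(sim, "data/cohort")

rar <- rarefy(sim$otu, cfg$rarefy_depth, seed = seed)
write_otu_table(rar, "data/cohort/otu_counts_rarefied.tsv",
                "data/cohort/otu_taxonomy_rarefied.tsv")
writeLines(c(sprintf("seed: %d", seed),
             sprintf("rarefy_depth: %d", as.integer(cfg$rarefy_depth)),
             sprintf("dropped_samples: %s",
                     paste(attr(rar, "dropped"), collapse = ","))),
           "data/cohort/run_info.txt")
cat("cohort written to data/cohort (", ncol(rar$counts), "samples )\n")
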