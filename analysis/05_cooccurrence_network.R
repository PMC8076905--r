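#!/usr/bin/env Rscript
# Genus-level SparCC co-occurrence network with permutation p-values,
# trait correlations, and betweenness-ranked keystone genera.
suppressPackageStartupMessages(library(rumenstab))

seed <- 42L
rar <- read_otu_table("data/cohort/otu_counts_rarefied.tsv",
                      "data/cohort/otu_taxonomy_rarefied.tsv")
ph <- read_phenotypes("data/cohort/phenotypes.csv")
scfa <- read_scfa("data/cohort/scfa.csv")

genus <- filter_taxa(collapse_taxonomy(rar, "genus"), 0.001)
grel <- relative_abundance(genus)

traits <- merge(scfa, ph, by = "sample_id")
traits <- traits[match(genus$sample_ids, traits$sample_id), ]
tc <- trait_correlations(grel, traits[, setdiff(names(traits), "sample_id")])
dir.create("results", showWarnings = FALSE)
write.table(data.frame(taxon = rownames(tc$r), tc$r, check.names = FALSE),
            "results/trait_correlations_r.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

est <- sparcc(genus$counts, seed = seed + 1L)
pmat <- sparcc_pvalues(genus$counts, est, n_permutations = 1000,
                       seed = seed + 2L)
net <- build_network(est, pmat, rowMeans(grel))
write_network(net, "results")
if (nrow(net$nodes) >= 3) {
  keys <- betweenness_keystones(net)
  write.table(keys, "results/keystones.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat("top keystones:\n"); print(head(keys, 5))
} else {
  cat("network too small for keystone ranking (",
      nrow(net$nodes), "nodes )\n")
}
cat(sprintf("network: %d nodes, %d edges\n", nrow(net$nodes), nrow(net$edges)))
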