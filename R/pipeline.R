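#' Run the full analysis pipeline on a simulated cohort
#'
#' Chains the stages in dependency order on synthetic data: simulate ->
#' rarefy -> per-OTU stability -> per-OTU phenotype screen (all cows and both
#' parity strata) -> lactation-stage / diversity / B-F trends -> trait
#' correlations -> SparCC co-occurrence network with keystone ranking. Every
#' numeric output is reproducible from the configuration and seed alone; a
#' manifest recording inputs, parameters and seed is written alongside the
#' outputs.
#'
#' @param config [sim_config()] describing the cohort.
#' @param out_dir output directory for the stage TSVs (created); `NULL` skips
#'   writing.
#' @param depth rarefaction depth (default taken from the config).
#' @param alpha family-wise error rate for the screen.
#' @param c_threshold,p_threshold stability rule thresholds.
#' @param abundance_filter genus mean relative-abundance threshold.
#' @param r_threshold network correlation threshold.
#' @param n_permutations SparCC permutation count (default 1000).
#' @param phenotype_names phenotypes to screen (default fat_pct and
#'   protein_pct; the full five-trait screen is available but slower).
#' @return list with elements `cohort`, `rarefied`, `stability`, `summary`,
#'   `screen` (list by cohort), `tukey`, `alpha_diversity`, `paired_tests`,
#'   `bf_trends`, `trait_correlations`, `sparcc`, `network`, `keystones`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         depth = config$rarefy_depth, alpha = 0.05,
                         c_threshold = 0.5, p_threshold = 0.05,
                         abundance_filter = 0.001, r_threshold = 0.5,
                         n_permutations = 1000,
                         phenotype_names = c("fat_pct", "protein_pct")) {
  derived_seed <- function(k)  # stays within the 32-bit integer range
    as.integer((as.numeric(config$seed) + k) %% 2147483647)
  cohort <- simulate_cohort(config)
  rar <- rarefy(cohort$otu, depth, seed = derived_seed(101))
  md <- cohort$metadata[cohort$metadata$sample_id %in% rar$sample_ids, ]

  stab <- assess_stability(rar, md, c_threshold, p_threshold)
  summ <- stability_summary(stab)

  screens <- lapply(c(all = "all", multiparous = "multiparous",
                      primiparous = "primiparous"), function(coh)
    screen_all(rar, md, cohort$phenotypes, phenotype_names, cohort = coh,
               alpha = alpha))

  phylum <- collapse_taxonomy(rar, "phylum")
  rel_ph <- relative_abundance(phylum)
  tukey <- tukey_stage_comparison(rel_ph, md$stage[match(phylum$sample_ids,
                                                         md$sample_id)])
  adiv <- alpha_diversity(rar)
  paired <- lapply(c(multiparous = "multiparous", primiparous = "primiparous"),
                   function(coh) {
    sub <- md[md$parity_class == coh, ]
    pr <- pair_samples(rar, sub)
    a1 <- adiv[match(colnames(pr$x1), adiv$sample_id), ]
    a2 <- adiv[match(colnames(pr$x2), adiv$sample_id), ]
    list(chao1 = paired_ttest(a1$chao1, a2$chao1),
         observed_species = paired_ttest(a1$observed_species,
                                         a2$observed_species))
  })
  bf <- bf_ratio(rar)
  bf_md <- merge(bf, md, by = "sample_id")
  bf_fits <- do.call(rbind, lapply(unique(bf_md$parity_class), function(coh) {
    sub <- bf_md[bf_md$parity_class == coh, ]
    bf_trend(sub$bf_ratio, sub$dim, coh)
  }))

  genus <- filter_taxa(collapse_taxonomy(rar, "genus"), abundance_filter)
  grel <- relative_abundance(genus)
  traits <- merge(cohort$scfa, cohort$phenotypes, by = "sample_id")
  traits <- traits[match(genus$sample_ids, traits$sample_id), ]
  tc <- trait_correlations(grel, traits[, setdiff(names(traits), "sample_id")])

  sp <- sparcc(genus$counts, seed = derived_seed(202))
  pmat <- sparcc_pvalues(genus$counts, sp, n_permutations = n_permutations,
                         seed = derived_seed(303))
  net <- build_network(sp, pmat, rowMeans(grel), r_threshold, p_threshold)
  keys <- if (nrow(net$nodes) >= 3) betweenness_keystones(net) else
    data.frame(taxon = character(), betweenness = numeric())

  out <- list(cohort = cohort, rarefied = rar, stability = stab,
              summary = summ, screen = screens, tukey = tukey,
              alpha_diversity = adiv, paired_tests = paired, bf_trends = bf_fits,
              trait_correlations = tc, sparcc = sp, sparcc_p = pmat,
              network = net, keystones = keys)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, config,
                                                n_permutations, depth)
  out
}

write_pipeline_outputs <- function(res, out_dir, config, n_permutations, depth) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(res$stability, "stability.tsv")
  tsv(res$summary$histogram, "stability_histogram.tsv")
  for (coh in names(res$screen))
    tsv(res$screen[[coh]], paste0("screen_", coh, ".tsv"))
  tsv(res$tukey, "tukey_stage.tsv")
  tsv(res$alpha_diversity, "alpha_diversity.tsv")
  tsv(res$bf_trends, "bf_trends.tsv")
  tsv(data.frame(taxon = rownames(res$trait_correlations$r),
                 res$trait_correlations$r, check.names = FALSE),
      "trait_correlations_r.tsv")
  write_network(res$network, out_dir)
  tsv(res$keystones, "keystones.tsv")
  manifest <- c(
    sprintf("seed: %d", config$seed),
    sprintf("n_cows: %d", config$n_cows),
    sprintf("n_otus: %d", config$n_otus),
    sprintf("stable_fraction: %g", config$stable_fraction),
    sprintf("rarefaction_depth: %d", as.integer(depth)),
    sprintf("dropped_samples: %s",
            paste(attr(res$rarefied, "dropped"), collapse = ",")),
    sprintf("n_permutations: %d", as.integer(n_permutations)),
    sprintf("n_network_edges: %d", nrow(res$network$edges)),
    sprintf("n_stable: %d", res$summary$n_stable),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("rumenstab"))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
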