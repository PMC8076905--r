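# rumenstab

Temporal stability and host-phenotype association analysis of the dairy-cow
rumen microbiome.

## Scientific problem

Repeated-measures 16S rRNA surveys of the rumen ask whether a cow's
microbiome is an individual trait: when the same cows are sampled twice
during lactation, which OTUs keep a stable within-cow abundance, and do any
of them associate with milk production or methane phenotypes? `rumenstab`
implements the full statistical pipeline for such a two-visit cohort:

1. **Temporal stability** — per-OTU agreement between visits by Lin's
   concordance correlation coefficient
   `C = 2ρσ₁σ₂ / (σ₁² + σ₂² + (μ₁−μ₂)²)`; an OTU is *stable* when
   `C > 0.5` and the Pearson correlation has `p < 0.05`.
2. **Phenotype screen** — per-OTU linear mixed model
   `y = μ + b_d·DIM + b_j·ln(rarefied count + 1) + parity + cow + e`
   (cow as random intercept, REML, Satterthwaite df), Bonferroni-controlled
   over the full OTU table, overall and stratified by parity.
3. **Composition over lactation** — Tukey HSD of taxon abundance across
   lactation stages (early `[1,50)`, mid `[50,100)`, late `[100,∞)` days in
   milk), Chao1/observed-species alpha diversity with paired tests between
   visits, and Bacteroidetes/Firmicutes-ratio trends on DIM.
4. **Co-occurrence** — SparCC compositional correlations (implemented from
   first principles) with permutation p-values, an edge rule of `|ρ| > 0.5`
   and `p < 0.05`, and keystone genera ranked by betweenness centrality.
5. **Synthetic cohorts** — a two-visit generator with known ground truth
   (designed-stable OTUs, injected phenotype effects, null phenotypes) used
   to validate calibration and power of every stage.

The methods vignette (`vignettes/rumenstab-methods.Rmd`) documents each
model, the numerical choices, and the generator's scope and limits.

## Worked example

Simulate a study-scale cohort (60 cows × 2 visits, 1,000 OTUs, 5 % designed
stable, five OTUs with true phenotype effects), rarefy, and run the stages:

```r
library(rumenstab)

cfg <- sim_config(seed = 42L,
                  causal_otus = data.frame(
                    otu = c(17, 204, 561, 88, 902),
                    phenotype = c("fat_pct", "fat_pct", "fat_pct",
                                  "protein_pct", "protein_pct"),
                    effect = c(1.5, 1.5, 1.5, 1.2, 1.2)))
sim <- simulate_cohort(cfg)
rar <- rarefy(sim$otu, cfg$rarefy_depth, seed = 42L)

stab <- assess_stability(rar, sim$metadata)
stability_summary(stab)$n_stable
#> [1] 50                      # 50 / 1000 = 5.0 %, matching the design

scr <- screen_all(rar, sim$metadata, sim$phenotypes,
                  c("fat_pct", "protein_pct"))
scr[scr$significant, c("otu_id", "phenotype", "estimate", "p_value")]
#>        otu_id   phenotype estimate      p_value
#> 17   OTU_0017     fat_pct 1.522856 9.109144e-10
#> 204  OTU_0204     fat_pct 1.355833 3.669979e-08
#> 561  OTU_0561     fat_pct 1.809472 1.148238e-17
#> 1088 OTU_0088 protein_pct 1.202372 4.586457e-17
#> 1902 OTU_0902 protein_pct 1.128944 4.992752e-18
```

All five injected OTUs are recovered at the Bonferroni threshold
(`0.05 / 1000`, baseline −log₁₀ p = 4.30) with estimates near their true
effects, and no false positives. The same cohort's B/F-ratio trend:

```r
bf <- merge(bf_ratio(rar), sim$metadata, by = "sample_id")
sub <- bf[bf$parity_class == "primiparous", ]
bf_trend(sub$bf_ratio, sub$dim, "primiparous")
#>        cohort        slope intercept  r_squared   p_value  n
#> 1 primiparous -0.001253278  2.840981 0.02510599 0.2524753 54
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the whole study
on a simulated cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # cohort + rarefied table -> data/cohort
Rscript analysis/02_stability.R            # stability.tsv, histogram, stable genera
Rscript analysis/03_phenotype_screen.R     # screen_{all,multiparous,primiparous}.tsv
Rscript analysis/04_composition_trends.R   # tukey_stage, alpha diversity, B/F trends
Rscript analysis/05_cooccurrence_network.R # SparCC network, keystones
```

The complete run takes under a minute. A one-call equivalent is
`run_pipeline(sim_config(seed = 42L), out_dir = "results")`.

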