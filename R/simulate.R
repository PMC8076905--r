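#' Configuration for the synthetic two-visit cohort
#'
#' The generator emulates the study design the package targets: ~60 lactating
#' Holstein cows (27 primiparous, 33 multiparous), each sampled twice with a
#' 122-day interval, first-visit DIM between 13 and 198 so that all DIM fall
#' in 13-320. Per-OTU stability is injected on the latent log-abundance
#' scale: ground-truth-stable OTUs share the between-visit cow effect with
#' high correlation (`rho_stable`), unstable OTUs draw (nearly) independent
#' visit values and receive a random between-visit mean shift, so the
#' concordance statistic is exercised through the full multinomial sampling
#' chain. Phenotypes follow the screening model itself:
#' y = mu + b_dim * dim + sum(effect * ln(rarefied count + 1)) + parity +
#' animal + noise. SCFA are baseline + linear contributions from designated
#' genera (on standardized genus abundance) + Gaussian noise, so trait-taxon
#' correlations are recoverable by construction.
#'
#' @param n_cows,n_primiparous cohort size and its primiparous subset
#'   (defaults 60 and 27; the primiparous share scales with `n_cows`).
#' @param n_otus number of OTUs.
#' @param stable_fraction fraction of OTUs designed stable (default 0.05).
#' @param library_size_mean,library_size_cv per-sample sequencing depth
#'   distribution (normal, truncated at 1000 reads).
#' @param visit_interval_days days between the two samplings (default 122).
#' @param dim_min,dim_max first-visit DIM range (defaults 13, 198).
#' @param rarefy_depth depth used internally for the causal phenotype term
#'   and intended for downstream rarefaction (default 76000).
#' @param base_log_mean,base_log_sd per-OTU baseline log-abundance
#'   distribution.
#' @param cow_sd latent between-cow standard deviation per OTU.
#' @param rho_stable,rho_unstable between-visit latent correlation for
#'   stable/unstable OTUs.
#' @param unstable_shift_sd SD of the per-OTU visit-2 mean shift added to
#'   unstable OTUs.
#' @param bf_dim_effect per-day latent trend applied to Bacteroidetes OTUs in
#'   primiparous cows (emulates the declining B/F ratio in first-lactation
#'   cows; set 0 to disable).
#' @param causal_otus data.frame `otu` (index), `phenotype`, `effect`, or
#'   `NULL` for no OTU-phenotype effects. Effect sizes have no empirical
#'   anchor and are arbitrary.
#' @param causal_cohort `"all"`, `"multiparous"` or `"primiparous"`: cows in
#'   which the causal effects act.
#' @param phenotype_params named list per phenotype with `mu`, `b_dim`,
#'   `parity` (length-3 effects for parity 1-3), `sigma2_B`, `sigma2_e`.
#' @param scfa_effects named list acid -> named vector of per-genus
#'   contributions (applied to standardized genus relative abundance).
#' @param scfa_noise_sd Gaussian noise SD per acid (mmol/kg).
#' @param domain_tag `"bacteria"` or `"archaea"` (selects the taxonomy pool).
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cows = 60, n_primiparous = round(0.45 * n_cows),
                       n_otus = 1000,
                       stable_fraction = 0.05,
                       library_size_mean = 1e5, library_size_cv = 0.08,
                       visit_interval_days = 122,
                       dim_min = 13, dim_max = 198,
                       rarefy_depth = 76000,
                       base_log_mean = 0, base_log_sd = 1.5,
                       cow_sd = 1, rho_stable = 0.95, rho_unstable = 0,
                       unstable_shift_sd = 0.5,
                       bf_dim_effect = -0.0015,
                       causal_otus = NULL, causal_cohort = "all",
                       phenotype_params = default_phenotype_params(),
                       scfa_effects = default_scfa_effects(),
                       scfa_noise_sd = 1,
                       domain_tag = "bacteria",
                       seed = 1L) {
  if (n_primiparous > n_cows) stop("n_primiparous must be <= n_cows")
  if (stable_fraction < 0 || stable_fraction > 1)
    stop("stable_fraction must lie in [0, 1]")
  if (cow_sd < 0) stop("variances must be >= 0")
  if (!is.null(causal_otus)) {
    causal_otus <- as.data.frame(causal_otus)
    stopifnot(all(c("otu", "phenotype", "effect") %in% names(causal_otus)),
              all(causal_otus$otu >= 1), all(causal_otus$otu <= n_otus))
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

default_phenotype_params <- function() list(
  milk_yield  = list(mu = 32,  b_dim = -0.03,  parity = c(0, 4, 6),    sigma2_B = 16,   sigma2_e = 4),
  ecm         = list(mu = 33,  b_dim = -0.03,  parity = c(0, 4, 6),    sigma2_B = 16,   sigma2_e = 4),
  fat_pct     = list(mu = 4.0, b_dim = 0.002,  parity = c(0, 0.1, 0.15), sigma2_B = 0.16, sigma2_e = 0.09),
  protein_pct = list(mu = 3.4, b_dim = 0.002,  parity = c(0, 0.05, 0.08), sigma2_B = 0.04, sigma2_e = 0.02),
  methane     = list(mu = 400, b_dim = 0.1,    parity = c(0, 30, 40),  sigma2_B = 1600, sigma2_e = 400))

default_scfa_effects <- function() list(
  acetate    = c(Prevotella = 2),
  propionate = c(Fibrobacter = 1.5),
  butyrate   = c(Butyrivibrio = 1.5))

# rumen-flavoured lineage pools; weights shape the phylum composition toward
# the Bacteroidetes-dominated profile typical of lactating cows
bacteria_lineages <- function() {
  lin <- c(
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;;",
    "Bacteria;Bacteroidetes;;;;",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Butyrivibrio",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Ruminococcus",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;",
    "Bacteria;Firmicutes;Negativicutes;Selenomonadales;Veillonellaceae;Succiniclasticum",
    "Bacteria;Fibrobacteres;Fibrobacteria;Fibrobacterales;Fibrobacteraceae;Fibrobacter",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Aeromonadales;Succinivibrionaceae;Succinivibrio",
    "Bacteria;SR1;;;;",
    "Bacteria;Tenericutes;Mollicutes;Anaeroplasmatales;Anaeroplasmataceae;Anaeroplasma")
  w <- c(0.33, 0.12, 0.15, 0.05, 0.06, 0.05, 0.06, 0.04, 0.03, 0.04, 0.03, 0.02, 0.02)
  list(lineages = lin, weights = w / sum(w))
}

archaea_lineages <- function() {
  lin <- c(
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter",
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanosphaera",
    "Archaea;Euryarchaeota;Thermoplasmata;E2;Methanomassiliicoccaceae;vadinCA11",
    "Archaea;Euryarchaeota;Thermoplasmata;E2;Methanomassiliicoccaceae;",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanosarcina")
  w <- c(0.55, 0.15, 0.12, 0.1, 0.08)
  list(lineages = lin, weights = w / sum(w))
}

#' Simulate a two-visit cohort with known ground truth
#'
#' See [sim_config()] for the generative model. Returns the raw (unrarefied)
#' count table, metadata, phenotypes, SCFA concentrations and the ground
#' truth (per-OTU stable labels, the causal map, realized animal effects).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `otu` ([otu_table()]), `metadata`,
#'   `phenotypes`, `scfa`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n_samples <- 2L * cfg$n_cows
    cow_ids <- sprintf("cow%03d", seq_len(cfg$n_cows))
    parity <- c(rep(1L, cfg$n_primiparous),
                sample(2:4, cfg$n_cows - cfg$n_primiparous, replace = TRUE))
    dim1 <- round(stats::runif(cfg$n_cows, cfg$dim_min, cfg$dim_max))
    metadata <- data.frame(
      sample_id = paste0(rep(cow_ids, each = 2), "_t", rep(1:2, cfg$n_cows)),
      cow_id = rep(cow_ids, each = 2),
      parity = rep(parity, each = 2),
      dim = as.integer(rbind(dim1, dim1 + cfg$visit_interval_days)),
      sampling_event = rep(1:2, cfg$n_cows),
      stringsAsFactors = FALSE)
    metadata <- validate_metadata(metadata)

    # taxonomy and ground-truth stability labels
    pool <- if (cfg$domain_tag == "archaea") archaea_lineages() else bacteria_lineages()
    lin_idx <- sample(seq_along(pool$lineages), cfg$n_otus,
                      replace = TRUE, prob = pool$weights)
    taxonomy <- parse_lineage(pool$lineages[lin_idx])
    otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
    n_stable <- round(cfg$stable_fraction * cfg$n_otus)
    stable <- rep(FALSE, cfg$n_otus)
    stable[sample(cfg$n_otus, n_stable)] <- TRUE

    # latent log abundances: z[o, sample] = base + visit shift (unstable) +
    # parity-specific DIM trend (Bacteroidetes) + correlated cow effect
    base <- stats::rnorm(cfg$n_otus, cfg$base_log_mean, cfg$base_log_sd)
    shift <- ifelse(stable, 0, stats::rnorm(cfg$n_otus, 0, cfg$unstable_shift_sd))
    rho <- ifelse(stable, cfg$rho_stable, cfg$rho_unstable)
    u <- matrix(stats::rnorm(cfg$n_otus * cfg$n_cows, 0, cfg$cow_sd),
                cfg$n_otus, cfg$n_cows)
    eps1 <- matrix(stats::rnorm(cfg$n_otus * cfg$n_cows, 0, cfg$cow_sd),
                   cfg$n_otus, cfg$n_cows)
    eps2 <- matrix(stats::rnorm(cfg$n_otus * cfg$n_cows, 0, cfg$cow_sd),
                   cfg$n_otus, cfg$n_cows)
    sr <- sqrt(rho); sc <- sqrt(1 - rho)
    z1 <- base + sr * u + sc * eps1
    z2 <- base + shift + sr * u + sc * eps2
    if (cfg$bf_dim_effect != 0 && cfg$domain_tag == "bacteria") {
      is_bact <- !is.na(taxonomy$phylum) & taxonomy$phylum == "Bacteroidetes"
      prim <- parity == 1
      d1 <- matrix(rep(dim1, each = cfg$n_otus), cfg$n_otus)
      d2 <- d1 + cfg$visit_interval_days
      trend <- cfg$bf_dim_effect * outer(is_bact, prim)
      z1 <- z1 + trend * d1
      z2 <- z2 + trend * d2
    }
    z <- matrix(0, cfg$n_otus, n_samples)
    z[, seq(1, n_samples, 2)] <- z1
    z[, seq(2, n_samples, 2)] <- z2

    # closed composition + multinomial counting at the drawn library size
    lib <- pmax(1000, round(stats::rnorm(
      n_samples, cfg$library_size_mean,
      cfg$library_size_cv * cfg$library_size_mean)))
    fracs <- apply(z, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
    counts <- matrix(0, cfg$n_otus, n_samples,
                     dimnames = list(otu_ids, metadata$sample_id))
    for (j in seq_len(n_samples))
      counts[, j] <- stats::rmultinom(1, lib[j], fracs[, j])
    otu <- otu_table(counts, taxonomy, cfg$domain_tag)

    # causal phenotype term uses the same transform as the screen, on counts
    # rarefied at the configured depth (samples below depth fall back to raw)
    lx <- NULL
    if (!is.null(cfg$causal_otus) && nrow(cfg$causal_otus)) {
      depth <- min(cfg$rarefy_depth, min(colSums(counts)))
      rar <- suppressMessages(rarefy(otu, depth,
        seed = as.integer((as.numeric(cfg$seed) + 1) %% 2147483647)))
      lx <- log(rar$counts[, metadata$sample_id, drop = FALSE] + 1)
    }

    # phenotypes from the screening model
    phen <- data.frame(sample_id = metadata$sample_id, stringsAsFactors = FALSE)
    animal_effects <- list()
    causal_on <- if (cfg$causal_cohort == "all") rep(TRUE, nrow(metadata))
                 else metadata$parity_class == cfg$causal_cohort
    for (ph in names(cfg$phenotype_params)) {
      pp <- cfg$phenotype_params[[ph]]
      a <- stats::rnorm(cfg$n_cows, 0, sqrt(pp$sigma2_B))
      names(a) <- cow_ids
      y <- pp$mu + pp$b_dim * metadata$dim +
        pp$parity[pmin(metadata$parity, 3L)] +
        a[metadata$cow_id] +
        stats::rnorm(nrow(metadata), 0, sqrt(pp$sigma2_e))
      if (!is.null(lx)) {
        rows <- cfg$causal_otus[cfg$causal_otus$phenotype == ph, , drop = FALSE]
        for (r in seq_len(nrow(rows)))
          y <- y + ifelse(causal_on, rows$effect[r] * lx[rows$otu[r], ], 0)
      }
      phen[[ph]] <- unname(y)
      animal_effects[[ph]] <- a
    }
    phen$fat_pct <- pmin(pmax(phen$fat_pct, 0), 100)
    phen$protein_pct <- pmin(pmax(phen$protein_pct, 0), 100)
    phen$milk_yield <- pmax(phen$milk_yield, 0)
    phen$ecm <- pmax(phen$ecm, 0)
    phen$methane <- pmax(phen$methane, 0)

    # SCFA: baseline + standardized-genus contributions + noise
    genus <- collapse_taxonomy(otu, "genus")
    grel <- relative_abundance(genus)
    baselines <- c(acetate = 62, propionate = 20, butyrate = 13,
                   isobutyrate = 1.5, valerate = 2, isovalerate = 1.5)
    scfa <- data.frame(sample_id = metadata$sample_id, stringsAsFactors = FALSE)
    for (acid in names(baselines)) {
      v <- baselines[[acid]] +
        stats::rnorm(n_samples, 0, cfg$scfa_noise_sd)
      eff <- cfg$scfa_effects[[acid]]
      for (g in names(eff)) {
        row <- match(g, genus$otu_ids)
        if (!is.na(row) && stats::sd(grel[row, ]) > 0)
          v <- v + eff[[g]] * as.numeric(scale(grel[row, ]))
      }
      scfa[[acid]] <- pmax(v, 0.1)
    }

    truth <- list(
      stable_labels = data.frame(otu_id = otu_ids, stable = stable,
                                 stringsAsFactors = FALSE),
      causal = if (is.null(cfg$causal_otus)) {
        data.frame(otu_id = character(), phenotype = character(),
                   effect = numeric(), stringsAsFactors = FALSE)
      } else {
        data.frame(otu_id = otu_ids[cfg$causal_otus$otu],
                   phenotype = cfg$causal_otus$phenotype,
                   effect = cfg$causal_otus$effect, stringsAsFactors = FALSE)
      },
      animal_effects = animal_effects,
      config = cfg)

    structure(list(otu = otu, metadata = metadata, phenotypes = phen,
                   scfa = scfa, truth = truth),
              class = "sim_cohort")
  })
}

#' Simulate phenotypes with no OTU effects
#'
#' Convenience wrapper for type-I-error harnesses: forces an empty causal map
#' so phenotypes are independent of all OTU abundances given DIM, parity and
#' animal.
#'
#' @param config a [sim_config()].
#' @return the phenotype table of the null cohort; the full cohort is
#'   attached as attribute `"cohort"`.
#' @export
simulate_null_phenotype <- function(config = sim_config()) {
  config$causal_otus <- NULL
  sim <- simulate_cohort(config)
  structure(sim$phenotypes, cohort = sim)
}

#' Write a simulated cohort in the formats the readers accept
#'
#' @param cohort `sim_cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("otu_counts.tsv", "otu_taxonomy.tsv",
                            "metadata.csv", "phenotypes.csv", "scfa.csv",
                            "truth.csv"))
  write_otu_table(cohort$otu, paths[1], paths[2])
  utils::write.csv(cohort$metadata[, c("sample_id", "cow_id", "parity",
                                       "dim", "sampling_event")],
                   paths[3], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$phenotypes, paths[4], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$scfa, paths[5], row.names = FALSE, quote = FALSE)
  tr <- merge(cohort$truth$stable_labels, cohort$truth$causal,
              by = "otu_id", all.x = TRUE)
  utils::write.csv(tr, paths[6], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
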