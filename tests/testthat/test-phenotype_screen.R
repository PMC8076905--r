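test_that("Bonferroni threshold is alpha/n with its Manhattan baseline", {
  b <- bonferroni_threshold(0.05, 6363)
  expect_equal(b$threshold, 0.05 / 6363)
  expect_equal(b$threshold, 7.858e-6, tolerance = 1e-3)
  expect_equal(b$neg_log10, 5.105, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(0.05, 79)$threshold, 6.329e-4, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
})

test_that("a constant OTU covariate is non-estimable", {
  md <- toy_metadata(10)
  fit <- fit_otu_model(rnorm(20), md$dim, md$parity, md$cow_id,
                       rep(7, 20))
  expect_equal(fit$fit_status, "non-estimable")
  expect_true(is.na(fit$p_value))
})

test_that("REML fit matches lme4 and collapses to OLS when sigma2_B = 0", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_cows = 40, n_otus = 20, library_size_mean = 20000,
                    rarefy_depth = 15000, seed = 21)
  sim <- simulate_cohort(cfg)
  rar <- suppressMessages(rarefy(sim$otu, 15000, seed = 21))
  md <- sim$metadata[match(rar$sample_ids, sim$metadata$sample_id), ]
  ph <- sim$phenotypes[match(rar$sample_ids, sim$phenotypes$sample_id), ]
  for (i in c(2, 9, 17)) {
    cnt <- rar$counts[i, ]
    mine <- fit_otu_model(ph$fat_pct, md$dim, md$parity, md$cow_id, cnt)
    d <- data.frame(y = ph$fat_pct, dim = md$dim,
                    pf = factor(pmin(md$parity, 3)), lx = log(cnt + 1),
                    cow = md$cow_id)
    ref <- lme4::lmer(y ~ dim + pf + lx + (1 | cow), data = d, REML = TRUE)
    expect_equal(mine$estimate, unname(lme4::fixef(ref)[["lx"]]), tolerance = 1e-5)
    expect_equal(mine$se, sqrt(as.matrix(lme4::vcov.merMod(ref))["lx", "lx"]),
                 tolerance = 1e-5)
    if (requireNamespace("lmerTest", quietly = TRUE)) {
      refl <- lmerTest::as_lmerModLmerTest(ref)
      sml <- coef(summary(refl))["lx", ]
      expect_equal(mine$df, unname(sml[["df"]]), tolerance = 0.02)
      expect_equal(mine$p_value, unname(sml[["Pr(>|t|)"]]), tolerance = 0.01)
    }
  }

  # degenerate limit: no animal variance in the generator -> OLS coefficients
  cfg0 <- sim_config(n_cows = 60, n_otus = 10, library_size_mean = 20000,
                     rarefy_depth = 15000, seed = 22)
  for (p in names(cfg0$phenotype_params)) cfg0$phenotype_params[[p]]$sigma2_B <- 0
  sim0 <- simulate_cohort(cfg0)
  rar0 <- suppressMessages(rarefy(sim0$otu, 15000, seed = 22))
  md0 <- sim0$metadata[match(rar0$sample_ids, sim0$metadata$sample_id), ]
  ph0 <- sim0$phenotypes[match(rar0$sample_ids, sim0$phenotypes$sample_id), ]
  cnt <- rar0$counts[4, ]
  mine <- fit_otu_model(ph0$milk_yield, md0$dim, md0$parity, md0$cow_id, cnt)
  ols <- lm(ph0$milk_yield ~ md0$dim + factor(pmin(md0$parity, 3)) + log(cnt + 1))
  expect_equal(mine$estimate, unname(coef(ols)[5]), tolerance = 1e-6)
})

test_that("screening is per-OTU independent and row order does not matter", {
  cfg <- sim_config(n_cows = 20, n_otus = 30, library_size_mean = 10000,
                    rarefy_depth = 8000, seed = 31)
  sim <- simulate_cohort(cfg)
  rar <- suppressMessages(rarefy(sim$otu, 8000, seed = 31))
  md <- sim$metadata
  res <- screen_all(rar, md, sim$phenotypes, "milk_yield")
  perm <- sample(nrow(rar$counts))
  shuffled <- otu_table(rar$counts[perm, ], rar$taxonomy[perm, ], "bacteria")
  res2 <- screen_all(shuffled, md, sim$phenotypes, "milk_yield")
  res2 <- res2[match(res$otu_id, res2$otu_id), ]
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-12)
  expect_equal(res$estimate, res2$estimate, tolerance = 1e-12)
  # neg log p is monotone decreasing in p
  ok <- !is.na(res$p_value)
  expect_equal(order(res$neg_log10_p[ok]), order(-res$p_value[ok]))
})

test_that("null screens are calibrated and injected effects are recovered", {
  # null: p-values approximately uniform
  pvals <- c()
  for (s in 41:44) {
    cfg <- sim_config(n_cows = 50, n_otus = 100, library_size_mean = 20000,
                      rarefy_depth = 15000, seed = s)
    sim <- simulate_cohort(cfg)
    rar <- suppressMessages(rarefy(sim$otu, 15000, seed = s))
    res <- screen_all(rar, sim$metadata, sim$phenotypes, "protein_pct")
    pvals <- c(pvals, res$p_value[!is.na(res$p_value)])
  }
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)

  # power: a strongly associated OTU crosses the Bonferroni baseline
  cfg <- sim_config(n_cows = 50, n_otus = 100, library_size_mean = 20000,
                    rarefy_depth = 15000, seed = 45,
                    causal_otus = data.frame(otu = 10, phenotype = "fat_pct",
                                             effect = 2))
  sim <- simulate_cohort(cfg)
  rar <- suppressMessages(rarefy(sim$otu, 15000, seed = 45))
  res <- screen_all(rar, sim$metadata, sim$phenotypes, "fat_pct")
  hit <- res[res$otu_id == "OTU_0010", ]
  expect_true(hit$significant)
  expect_true(all(is.finite(c(hit$estimate, hit$se, hit$neg_log10_p))))
})

test_that("effects confined to multiparous cows vanish in the primiparous stratum", {
  cfg <- sim_config(n_cows = 50, n_otus = 80, library_size_mean = 20000,
                    rarefy_depth = 15000, seed = 46,
                    causal_otus = data.frame(otu = c(5, 12),
                                             phenotype = "fat_pct", effect = 1.5),
                    causal_cohort = "multiparous")
  sim <- simulate_cohort(cfg)
  rar <- suppressMessages(rarefy(sim$otu, 15000, seed = 46))
  multi <- screen_all(rar, sim$metadata, sim$phenotypes, "fat_pct",
                      cohort = "multiparous")
  prim <- screen_all(rar, sim$metadata, sim$phenotypes, "fat_pct",
                     cohort = "primiparous")
  expect_true(any(multi$significant[multi$otu_id %in% c("OTU_0005", "OTU_0012")]))
  expect_equal(sum(prim$significant), 0)
  expect_error(screen_all(rar, sim$metadata[0, ], sim$phenotypes, "fat_pct"),
               "empty cohort")
})
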