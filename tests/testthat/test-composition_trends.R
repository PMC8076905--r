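test_that("Tukey comparison matches TukeyHSD and an independent q computation", {
  y <- c(2.1, 2.5, 2.3, 3.8, 4.1, 3.9, 4.0, 1.2, 1.5, 1.1, 1.4)
  g <- c("early", "early", "early", "mid", "mid", "mid", "mid",
         "late", "late", "late", "late")
  res <- tukey_stage_comparison(matrix(y, 1, dimnames = list("tax", NULL)), g)
  # reference route: stats::aov + TukeyHSD
  ref <- TukeyHSD(aov(y ~ factor(g)))[[1]]
  for (i in seq_len(nrow(res))) {
    key <- paste(res$stage_b[i], res$stage_a[i], sep = "-")
    key2 <- paste(res$stage_a[i], res$stage_b[i], sep = "-")
    row <- if (key %in% rownames(ref)) ref[key, ] else ref[key2, ]
    expect_equal(res$p_adj[i], unname(row["p adj"]), tolerance = 1e-8)
  }
  # independent q: |mean diff| / sqrt((MSE/2)(1/na+1/nb)) from first principles
  groups <- split(y, g)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / (length(y) - 3)
  q_hand <- abs(mean(groups$early) - mean(groups$mid)) /
    sqrt(mse / 2 * (1 / 3 + 1 / 4))
  got <- res[res$stage_a == "early" & res$stage_b == "mid", ]
  expect_equal(got$q, q_hand, tolerance = 1e-10)
  expect_equal(got$p_adj, ptukey(q_hand, 3, length(y) - 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical stage distributions give adjusted p near 1; tiny stages are excluded", {
  vals <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  g <- rep(c("early", "mid", "late"), each = 3)
  res <- tukey_stage_comparison(matrix(vals, 1, dimnames = list("t", NULL)), g)
  expect_true(all(res$p_adj > 0.999))
  expect_warning(
    tukey_stage_comparison(matrix(c(vals, 5), 1, dimnames = list("t", NULL)),
                           c(g, "weird")),
    "excluded")
})

test_that("a taxon constructed to drop from mid to late is detected", {
  withr::with_seed(5, {
    stage <- rep(c("early", "mid", "late"), each = 12)
    ab <- c(rnorm(12, 0.05, 0.005), rnorm(12, 0.05, 0.005), rnorm(12, 0.02, 0.005))
    res <- tukey_stage_comparison(matrix(ab, 1, dimnames = list("SR1", NULL)), stage)
    ml <- res[(res$stage_a == "late" & res$stage_b == "mid") |
                (res$stage_a == "mid" & res$stage_b == "late"), ]
    expect_lt(ml$p_adj, 0.05)
  })
})

test_that("chao1 follows the bias-corrected formula and bounds observed richness", {
  # 5 singletons, 2 doubletons, 3 more abundant taxa
  counts <- c(1, 1, 1, 1, 1, 2, 2, 5, 9, 30)
  expect_equal(chao1(counts), 10 + 5 * 4 / (2 * 3))
  expect_equal(chao1(counts), 40 / 3, tolerance = 1e-12)
  # no singletons: estimator equals observed richness
  expect_equal(chao1(c(3, 4, 5)), 3)
  expect_equal(chao1(c(0, 3, 4, 5)), 3)
  expect_error(chao1(c(0, 0)), "empty")
  # always at least the observed count, on random samples
  withr::with_seed(8, {
    for (k in 1:30) {
      v <- rpois(50, 2)
      if (sum(v) == 0) next
      expect_gte(chao1(v), observed_species(v))
    }
  })
})

test_that("chao1 agrees with vegan's estimator", {
  skip_if_not_installed("vegan")
  withr::with_seed(12, {
    for (k in 1:10) {
      v <- rpois(100, 1.5)
      if (sum(v) == 0) next
      ref <- vegan::estimateR(v)[["S.chao1"]]
      expect_equal(chao1(v), unname(ref), tolerance = 1e-8)
    }
  })
})

test_that("paired t-test matches the textbook formula and flags degenerate input", {
  # alternating +1/-1 differences: zero mean difference
  r <- paired_ttest(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  withr::with_seed(33, {
    x <- rnorm(15); y <- x + rnorm(15, 0.4, 0.5)
    r <- paired_ttest(x, y)
    d <- y - x
    t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(r$t, t_hand, tolerance = 1e-10)
    expect_equal(r$p_value, 2 * pt(-abs(t_hand), length(d) - 1), tolerance = 1e-10)
  })
  # constant nonzero shift with tiny noise: decisive
  withr::with_seed(34, {
    x <- rnorm(10); y <- x + 1 + rnorm(10, sd = 0.01)
    expect_lt(paired_ttest(x, y)$p_value, 0.001)
  })
  # identical vectors: undefined, never a spurious p
  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$undefined)
  expect_true(is.na(same$p_value))
})

test_that("B/F trend recovers exact lines and closed-form R-squared", {
  dim <- c(20, 60, 100, 150, 220, 300)
  exact <- 2 - 0.01 * dim
  fit <- suppressWarnings(bf_trend(exact, dim, "primiparous"))
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- bf_trend(rep(2.5, 6) + c(1e-9, 0, -1e-9, 0, 1e-9, 0), dim)
  expect_equal(flat$slope, 0, tolerance = 1e-6)
  withr::with_seed(55, {
    y <- 3 - 0.008 * dim + rnorm(6, sd = 0.3)
    fit <- bf_trend(y, dim)
    sse <- sum(residuals(lm(y ~ dim))^2)
    sst <- sum((y - mean(y))^2)
    expect_equal(fit$r_squared, 1 - sse / sst, tolerance = 1e-12)
  })
  expect_error(bf_trend(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("alpha diversity keeps chao1 above observed species on rarefied data", {
  cfg <- sim_config(n_cows = 6, n_otus = 150, library_size_mean = 8000,
                    rarefy_depth = 6000, seed = 61)
  sim <- simulate_cohort(cfg)
  rar <- suppressMessages(rarefy(sim$otu, 6000, seed = 61))
  ad <- alpha_diversity(rar)
  expect_true(all(ad$chao1 >= ad$observed_species))
  expect_true(all(ad$observed_species >= 0))
})
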