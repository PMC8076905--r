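test_that("the abundance filter keeps taxa above 0.1% mean and is idempotent", {
  counts <- matrix(c(430, 430, 430,   # ~43%: Prevotella-like, kept
                     560, 560, 560,
                     9, 9, 9,         # 0.9%: kept
                     0.5, 0.5, 2) * 10, 4, 3, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  x <- otu_table(round(counts), NULL, "bacteria")
  f <- filter_taxa(x)
  expect_setequal(f$otu_ids, c("g1", "g2", "g3"))
  expect_identical(filter_taxa(f)$counts, f$counts)
  expect_error(filter_taxa(x, min_mean = 0.9), "filter")
})

test_that("trait correlations recover exact linear relations and match the formula", {
  withr::with_seed(71, {
    taxa <- matrix(runif(3 * 12), 3, 12, dimnames = list(paste0("g", 1:3), NULL))
    traits <- data.frame(up = 2 * taxa[1, ] + 1,
                         down = -3 * taxa[2, ] + 5,
                         noise = rnorm(12))
    tc <- trait_correlations(taxa, traits)
    expect_equal(unname(tc$r["g1", "up"]), 1, tolerance = 1e-12)
    expect_equal(unname(tc$r["g2", "down"]), -1, tolerance = 1e-12)
    # formula oracle on random data
    taxa2 <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("t", 1:5), NULL))
    traits2 <- as.data.frame(matrix(rnorm(10 * 4), 10, 4))
    tc2 <- trait_correlations(taxa2, traits2, p_threshold = 1.1)  # keep all rows
    for (i in 1:5) for (j in 1:4) {
      x <- taxa2[i, ]; y <- traits2[[j]]
      r_hand <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(unname(tc2$r[i, j]), r_hand, tolerance = 1e-12)
    }
    # rows without any nominally significant cell are dropped
    expect_true(all(apply(tc$p, 1, function(v) any(v < 0.05, na.rm = TRUE))))
  })
})

test_that("variation matrix matches brute-force log-ratio variances", {
  withr::with_seed(81, {
    fr <- matrix(rgamma(4 * 5, 2), 4, 5)
    fr <- sweep(fr, 2, colSums(fr), "/")
    expect_equal(variation_matrix(fr), brute_variation(fr), tolerance = 1e-12)
    expect_equal(diag(variation_matrix(fr)), rep(0, 4))
  })
})

test_that("SparCC output is symmetric with unit diagonal and compositionally invariant", {
  counts <- lognormal_counts(8, 40, seed = 5)
  est <- sparcc(counts, seed = 9)
  expect_equal(est$rho, t(est$rho))
  expect_equal(unname(diag(est$rho)), rep(1, 8))
  expect_true(all(abs(est$rho) <= 1))
  expect_true(all(est$t_matrix >= 0))
  # per-sample rescaling of counts leaves the estimate within sampling noise
  scaled <- round(sweep(counts, 2, rep(c(2, 5), 20), "*"))
  est2 <- sparcc(scaled, seed = 9)
  off <- upper.tri(est$rho)
  expect_lt(mean(abs(est$rho[off] - est2$rho[off])), 0.1)
  expect_error(sparcc(counts[1:3, ]), "4 taxa")
  expect_error(sparcc(counts[, 1:5]), "10 samples")
})

test_that("SparCC stays near zero on independent taxa and recovers an injected pair", {
  null_counts <- lognormal_counts(20, 100, seed = 15)
  est <- sparcc(null_counts, seed = 16)
  expect_lt(mean(abs(est$rho[upper.tri(est$rho)])), 0.15)
  sig <- lognormal_counts(20, 100, seed = 17, correlated_pair = c(3, 11))
  est2 <- sparcc(sig, seed = 18)
  expect_gt(est2$rho[3, 11], 0.6)
})

test_that("permutation p-values follow the add-one rule, are seed-reproducible and monotone", {
  counts <- lognormal_counts(6, 30, seed = 25, correlated_pair = c(1, 2))
  est <- sparcc(counts, n_inner = 5, seed = 26)
  p1 <- sparcc_pvalues(counts, est, n_permutations = 99, seed = 27, n_inner = 3)
  p2 <- sparcc_pvalues(counts, est, n_permutations = 99, seed = 27, n_inner = 3)
  expect_identical(p1, p2)
  off <- upper.tri(p1)
  expect_true(all(p1[off] > 0 & p1[off] <= 1))
  expect_equal(p1, t(p1))
  # the strongly correlated pair should beat (nearly) every permutation
  expect_lte(p1[1, 2], 5 / 100)
  # monotone in |rho_obs| on the same draws: inflate one cell's magnitude
  est_hi <- est
  est_hi$rho[3, 4] <- est_hi$rho[4, 3] <- 0.999
  p_hi <- sparcc_pvalues(counts, est_hi, n_permutations = 99, seed = 27, n_inner = 3)
  expect_lte(p_hi[3, 4], p1[3, 4])
})

test_that("network edges obey the strict |r| and p thresholds", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.6
  rho[1, 3] <- rho[3, 1] <- -0.55
  rho[2, 3] <- rho[2, 3] <- 0.6
  rho[2, 3] <- rho[3, 2] <- 0.6
  rho[1, 4] <- rho[4, 1] <- 0.4
  dimnames(rho) <- list(letters[1:4], letters[1:4])
  p <- matrix(0.01, 4, 4, dimnames = dimnames(rho))
  p[2, 3] <- p[3, 2] <- 0.2   # fails p
  est <- list(rho = rho)
  net <- build_network(est, p)
  keys <- paste(net$edges$source, net$edges$target)
  expect_setequal(keys, c("a b", "a c"))
  expect_equal(net$edges$sign[net$edges$target == "c"], "negative")
  expect_false("d" %in% net$nodes$taxon)  # |r|=0.4 never makes an edge
  # boundary cases are strict: r exactly 0.5 or p exactly 0.05 are excluded
  rho2 <- diag(3); rho2[1, 2] <- rho2[2, 1] <- 0.5
  rho2[1, 3] <- rho2[3, 1] <- 0.7
  dimnames(rho2) <- list(letters[1:3], letters[1:3])
  p2 <- matrix(0.01, 3, 3, dimnames = dimnames(rho2))
  p2[1, 3] <- p2[3, 1] <- 0.05
  net2 <- build_network(list(rho = rho2), p2)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(nrow(net2$nodes), 0)
})

test_that("betweenness matches canonical graphs and brute-force enumeration", {
  path <- igraph::make_graph(~ a - b, b - c)
  bk <- betweenness_keystones(path)
  expect_equal(bk$betweenness[bk$taxon == "b"], 1)
  expect_equal(sum(bk$betweenness[bk$taxon != "b"]), 0)
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:6)
  bs <- betweenness_keystones(star)
  expect_equal(bs$betweenness[bs$taxon == "v1"], 1)
  expect_true(all(bs$betweenness[bs$taxon != "v1"] == 0))
  withr::with_seed(91, {
    for (k in 1:5) {
      adj <- matrix(0, 8, 8)
      adj[upper.tri(adj)] <- rbinom(28, 1, 0.35)
      adj <- adj + t(adj)
      dimnames(adj) <- list(paste0("n", 1:8), paste0("n", 1:8))
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      got <- betweenness_keystones(g)
      want <- brute_betweenness(adj)
      expect_equal(got$betweenness[match(paste0("n", 1:8), got$taxon)],
                   want, tolerance = 1e-12)
    }
  })
})

test_that("network artifacts are written as edge list, node table and GraphML", {
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- 0.8; rho[2, 3] <- rho[3, 2] <- -0.7
  dimnames(rho) <- list(letters[1:3], letters[1:3])
  p <- matrix(0.001, 3, 3, dimnames = dimnames(rho))
  net <- build_network(list(rho = rho), p, abundance = c(a = 0.4, b = 0.3, c = 0.01))
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(file.path(dir, "network_edges.tsv"))
  expect_equal(nrow(edges), 2)
})
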