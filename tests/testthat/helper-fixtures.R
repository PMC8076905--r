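# in-code fixtures and independent oracles used across the suite

toy_counts <- function() {
  m <- matrix(c(10, 0, 5,
                20, 1, 5,
                30, 2, 0,
                0, 40, 90), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("otu", 1:4), paste0("s", 1:3)))
  m
}

toy_taxonomy <- function() {
  parse_lineage(c(
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Ruminococcus"))
}

toy_table <- function() otu_table(toy_counts(), toy_taxonomy(), "bacteria")

# two-visit metadata for n cows; sample ids <cow>_t<event>
toy_metadata <- function(n_cows = 3, parity = NULL, dim1 = NULL) {
  if (is.null(parity)) parity <- rep(1:2, length.out = n_cows)
  if (is.null(dim1)) dim1 <- seq(20, 20 + 10 * (n_cows - 1), by = 10)
  cows <- sprintf("cow%02d", seq_len(n_cows))
  data.frame(sample_id = paste0(rep(cows, each = 2), "_t", rep(1:2, n_cows)),
             cow_id = rep(cows, each = 2),
             parity = rep(parity, each = 2),
             dim = as.integer(rbind(dim1, dim1 + 122)),
             sampling_event = rep(1:2, n_cows),
             stringsAsFactors = FALSE) |> rumenstab:::validate_metadata()
}

# --- independent oracles ----------------------------------------------------

# direct evaluation of the concordance equation, coded without reusing the
# package's arithmetic path
ccc_direct <- function(x1, x2) {
  n <- length(x1)
  m1 <- sum(x1) / n; m2 <- sum(x2) / n
  v1 <- sum((x1 - m1)^2) / (n - 1); v2 <- sum((x2 - m2)^2) / (n - 1)
  cv <- sum((x1 - m1) * (x2 - m2)) / (n - 1)
  rho <- cv / sqrt(v1 * v2)
  2 * rho * sqrt(v1) * sqrt(v2) / (v1 + v2 + (m1 - m2)^2)
}

# brute-force normalized betweenness by enumerating every shortest path
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ] > 0)) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  D <- t(sapply(seq_len(n), dist_from))
  all_paths <- function(s, t) {
    if (!is.finite(D[s, t])) return(list())
    if (s == t) return(list(s))
    out <- list()
    for (w in which(adj[t, ] > 0)) {
      if (is.finite(D[s, w]) && D[s, w] == D[s, t] - 1) {
        for (p in all_paths(s, w)) out <- c(out, list(c(p, t)))
      }
    }
    out
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    for (p in paths) for (v in setdiff(p, c(s, t))) b[v] <- b[v] + 1 / length(paths)
  }
  b / ((n - 1) * (n - 2) / 2)
}

# brute-force log-ratio variation matrix, pair by pair
brute_variation <- function(fracs) {
  d <- nrow(fracs)
  out <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    if (i != j) out[i, j] <- stats::var(log(fracs[i, ] / fracs[j, ]))
  out
}

# multinomial counts from independent (or injected-correlation) log-normal
# basis abundances: the SparCC null/signal harness
lognormal_counts <- function(d, n, depth = 30000, seed = 1,
                             correlated_pair = NULL, pair_rho = 0.95) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(d * n), d, n)
    if (!is.null(correlated_pair)) {
      common <- stats::rnorm(n)
      for (i in correlated_pair)
        z[i, ] <- sqrt(pair_rho) * common + sqrt(1 - pair_rho) * stats::rnorm(n)
    }
    basis <- exp(z)
    fr <- sweep(basis, 2, colSums(basis), "/")
    counts <- sapply(seq_len(n), function(j) stats::rmultinom(1, depth, fr[, j]))
    rownames(counts) <- paste0("taxon", seq_len(d))
    counts
  })
}
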