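#' Filter genus-level taxa by mean relative abundance
#'
#' Retains taxa whose mean relative abundance across samples exceeds
#' `min_mean` (default 0.1%), the inclusion rule applied before trait
#' correlations and the co-occurrence network. Idempotent.
#'
#' @param x genus-level [otu_table()].
#' @param min_mean abundance threshold as a fraction (default 0.001).
#' @return filtered [otu_table()].
#' @export
filter_taxa <- function(x, min_mean = 0.001) {
  rel <- relative_abundance(x)
  keep <- rowMeans(rel) > min_mean
  if (!any(keep)) stop("no taxa pass the ", 100 * min_mean, "% abundance filter")
  otu_table(x$counts[keep, , drop = FALSE],
            x$taxonomy[keep, , drop = FALSE], x$domain_tag)
}

#' Pearson correlations between taxa and host traits
#'
#' Pairwise Pearson r and two-sided p-value between each (filtered) taxon's
#' relative abundance and each trait column (SCFA concentrations and
#' proportions, A:P ratio, milk traits, methane). Taxa with no nominally
#' significant cell (p < `p_threshold`) are dropped from the returned
#' matrices, mirroring heatmap-style reporting. Zero-variance columns give
#' `NA` cells.
#'
#' @param taxa matrix of relative abundances, taxa x samples.
#' @param traits data.frame/matrix of traits, samples x traits, row order
#'   matching the columns of `taxa`.
#' @param p_threshold row-retention threshold (default 0.05).
#' @return list `r`, `p` (taxa x traits matrices, retained rows only),
#'   `dropped` (taxa without any significant cell).
#' @export
trait_correlations <- function(taxa, traits, p_threshold = 0.05) {
  traits <- as.data.frame(traits)
  if (ncol(taxa) != nrow(traits))
    stop("taxa columns and trait rows must be sample-aligned")
  r <- p <- matrix(NA_real_, nrow(taxa), ncol(traits),
                   dimnames = list(rownames(taxa), names(traits)))
  for (i in seq_len(nrow(taxa))) {
    for (j in seq_len(ncol(traits))) {
      xv <- taxa[i, ]; yv <- traits[[j]]
      ok <- !is.na(xv) & !is.na(yv)
      if (sum(ok) >= 3 && stats::var(xv[ok]) > 0 && stats::var(yv[ok]) > 0) {
        ct <- stats::cor.test(xv[ok], yv[ok])
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  keep <- apply(p, 1, function(v) any(!is.na(v) & v < p_threshold))
  list(r = r[keep, , drop = FALSE], p = p[keep, , drop = FALSE],
       dropped = rownames(taxa)[!keep])
}

#' Log-ratio variation matrix
#'
#' t_ij = var(log(f_i / f_j)) across samples, the building block of the
#' SparCC basis-variance system. Symmetric with zero diagonal.
#'
#' @param fracs matrix of strictly positive fractions, taxa x samples.
#' @return D x D matrix.
#' @export
variation_matrix <- function(fracs) {
  L <- log(fracs)
  C <- stats::cov(t(L))
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0
  t_mat
}

# solve the sparsity-approximation linear system for basis variances omega;
# include is a logical D x D matrix of pairs still in the system
sparcc_basis <- function(t_mat, include) {
  m <- include * 1
  diag(m) <- rowSums(include)
  omega <- solve(m, rowSums(t_mat * include))
  pmax(omega, 1e-12)
}

# one SparCC correlation estimate from a fraction matrix (no resampling)
sparcc_core <- function(fracs, exclusion_threshold, n_exclusion_rounds) {
  d <- nrow(fracs)
  t_mat <- variation_matrix(fracs)
  include <- matrix(TRUE, d, d); diag(include) <- FALSE
  for (round in seq_len(n_exclusion_rounds + 1L)) {
    omega <- sparcc_basis(t_mat, include)
    rho <- (outer(omega, omega, "+") - t_mat) / (2 * sqrt(outer(omega, omega)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (round > n_exclusion_rounds) break
    cand <- abs(rho) * include
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    # never strip a taxon below 2 remaining partners (keeps the system solvable)
    if (sum(include[ij[1], ]) <= 2 || sum(include[ij[2], ]) <= 2) break
    include[ij[1], ij[2]] <- include[ij[2], ij[1]] <- FALSE
  }
  list(rho = rho, t_mat = t_mat, omega = omega)
}

#' SparCC compositional correlation estimate
#'
#' Estimates correlations between taxa from compositional counts following
#' the SparCC procedure: per inner iteration, taxon fractions are drawn from
#' a per-sample Dirichlet posterior with unit pseudocounts; the log-ratio
#' variation matrix t_ij is computed; basis variances omega are solved from
#' the sparsity-approximation linear system; correlations
#' rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j)) are
#' clipped to [-1, 1]; strongly correlated pairs exceeding
#' `exclusion_threshold` are iteratively removed from the system and it is
#' re-solved. The final estimate is the element-wise median over inner
#' iterations. Requires at least 4 taxa (the basis-variance system is not
#' identifiable below that) and at least 10 samples.
#'
#' @param counts matrix, taxa x samples (genus-level counts).
#' @param n_inner number of Dirichlet resampling iterations (default 20).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded from the basis system (default 0.1).
#' @param n_exclusion_rounds maximum exclusion iterations (default 10).
#' @param seed RNG seed; the estimate is deterministic given the seed.
#' @return list of class `sparcc_estimate`: `taxa`, `rho` (symmetric, unit
#'   diagonal), `t_matrix` and `omega` (element-wise medians over iterations).
#' @export
sparcc <- function(counts, n_inner = 20, exclusion_threshold = 0.1,
                   n_exclusion_rounds = 10, seed = 1L) {
  counts <- as.matrix(counts)
  d <- nrow(counts)
  if (d < 4)
    stop("SparCC needs >= 4 taxa: with D < 4 the basis-variance system is ",
         "underdetermined (D(D-1)/2 log-ratio variances cannot identify D ",
         "basis variances)")
  if (ncol(counts) < 10) stop("SparCC needs >= 10 samples")
  res <- withr::with_seed(seed,
    replicate(n_inner,
              sparcc_core(dirichlet_fractions(counts),
                          exclusion_threshold, n_exclusion_rounds),
              simplify = FALSE))
  rho <- apply(simplify2array(lapply(res, `[[`, "rho")), c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  t_mat <- apply(simplify2array(lapply(res, `[[`, "t_mat")), c(1, 2), stats::median)
  dimnames(t_mat) <- dimnames(rho)
  omega <- apply(do.call(rbind, lapply(res, `[[`, "omega")), 2, stats::median)
  structure(list(taxa = rownames(counts), rho = rho, t_matrix = t_mat,
                 omega = omega),
            class = "sparcc_estimate")
}

# one Dirichlet(counts + 1) draw per sample -> strictly positive fractions
dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), ncol(counts))
  sweep(g, 2, colSums(g), "/")
}

#' Permutation p-values for a SparCC estimate
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples (destroying all between-taxon dependence while preserving
#' marginals), recomputes the SparCC correlations, and compares magnitudes:
#' two-sided p = (#\{|rho_perm| >= |rho_obs|\} + 1) / (n_permutations + 1).
#' Reproducible under a fixed seed. Diagonal entries are `NA`.
#'
#' @param counts the matrix the estimate was computed on (taxa x samples).
#' @param estimate `sparcc_estimate` from [sparcc()].
#' @param n_permutations number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param n_inner Dirichlet iterations per permuted estimate (default 5;
#'   fewer than the observed estimate since only the magnitude null is
#'   needed).
#' @param exclusion_threshold,n_exclusion_rounds passed to the permuted
#'   re-estimates.
#' @return symmetric matrix of p-values in (0, 1].
#' @export
sparcc_pvalues <- function(counts, estimate, n_permutations = 1000, seed = 1L,
                           n_inner = 5, exclusion_threshold = 0.1,
                           n_exclusion_rounds = 10) {
  counts <- as.matrix(counts)
  obs <- abs(estimate$rho)
  exceed <- matrix(0, nrow(obs), ncol(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- t(apply(counts, 1, sample))
      res <- replicate(n_inner,
                       sparcc_core(dirichlet_fractions(perm),
                                   exclusion_threshold, n_exclusion_rounds)$rho,
                       simplify = FALSE)
      rho_b <- apply(simplify2array(res), c(1, 2), stats::median)
      exceed <- exceed + (abs(rho_b) >= obs)
    }
  })
  p <- (exceed + 1) / (n_permutations + 1)
  p <- (p + t(p)) / 2   # symmetrize counting asymmetries from the median
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(obs)
  p
}

#' Build the co-occurrence network
#'
#' Keeps an undirected edge for every taxon pair with |r| strictly above
#' `r_threshold` and p strictly below `p_threshold`; isolated taxa are
#' dropped. Node size attribute is the taxon's mean relative abundance.
#'
#' @param estimate `sparcc_estimate` (or any list with `rho`).
#' @param p_matrix matching p-value matrix.
#' @param abundance named vector of mean relative abundances per taxon
#'   (optional; `NA` when absent).
#' @param r_threshold,p_threshold edge thresholds (defaults 0.5, 0.05).
#' @return list of class `cooccurrence_network`: `nodes` (taxon, abundance),
#'   `edges` (source, target, r, p, sign), `graph` (igraph object).
#' @export
build_network <- function(estimate, p_matrix, abundance = NULL,
                          r_threshold = 0.5, p_threshold = 0.05) {
  rho <- estimate$rho
  taxa <- rownames(rho)
  idx <- which(upper.tri(rho) & abs(rho) > r_threshold &
                 !is.na(p_matrix) & p_matrix < p_threshold, arr.ind = TRUE)
  edges <- data.frame(source = taxa[idx[, 1]], target = taxa[idx[, 2]],
                      r = rho[idx], p = p_matrix[idx],
                      sign = ifelse(rho[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  used <- sort(unique(c(edges$source, edges$target)))
  ab <- if (is.null(abundance)) rep(NA_real_, length(used)) else unname(abundance[used])
  nodes <- data.frame(taxon = used, abundance = ab, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Keystone ranking by betweenness centrality
#'
#' Normalized shortest-path betweenness centrality (unweighted, undirected;
#' normalization 2/((n-1)(n-2))) per node, ranked descending. High-scoring
#' taxa are candidate keystones: they broker many shortest paths between
#' other community members.
#'
#' @param network `cooccurrence_network` from [build_network()] or an igraph
#'   object.
#' @return data.frame `taxon`, `betweenness`, sorted decreasing.
#' @export
betweenness_keystones <- function(network) {
  g <- if (inherits(network, "cooccurrence_network")) network$graph else network
  if (igraph::vcount(g) < 3) stop("betweenness ranking needs >= 3 nodes")
  b <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  out <- data.frame(taxon = names(b), betweenness = unname(b),
                    stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$taxon), , drop = FALSE]
}

#' Write network artifacts (edge list, node attributes, GraphML)
#'
#' @param network `cooccurrence_network`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("network_edges.tsv", "network_nodes.tsv",
                            "network.graphml"))
  utils::write.table(network$edges, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  igraph::write_graph(network$graph, paths[3], format = "graphml")
  invisible(paths)
}
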