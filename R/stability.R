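#' Pair each cow's two samples
#'
#' Aligns the rarefied count table into two cow-ordered matrices, one per
#' sampling event, keeping only cows with both samples present. The stability
#' assessment compares these paired per-cow abundance vectors OTU by OTU.
#'
#' @param x [otu_table()], typically rarefied.
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @return list with `x1`, `x2` (OTU x cow matrices, identical cow order),
#'   `cow_ids`, and `n` (number of complete pairs).
#' @export
pair_samples <- function(x, metadata) {
  md <- metadata[metadata$sample_id %in% x$sample_ids, ]
  s1 <- md[md$sampling_event == 1, ]
  s2 <- md[md$sampling_event == 2, ]
  cows <- sort(intersect(s1$cow_id, s2$cow_id))
  if (length(cows) < 3) stop("fewer than 3 cows with both sampling events")
  id1 <- s1$sample_id[match(cows, s1$cow_id)]
  id2 <- s2$sample_id[match(cows, s2$cow_id)]
  list(x1 = x$counts[, id1, drop = FALSE],
       x2 = x$counts[, id2, drop = FALSE],
       cow_ids = cows, n = length(cows))
}

#' Lin's concordance correlation coefficient for one OTU
#'
#' Agreement between the two sampling events is summarized as
#' \deqn{C = \frac{2\rho\sigma_1\sigma_2}{\sigma_1^2+\sigma_2^2+(\mu_1-\mu_2)^2}}
#' with sample (n-1) variances, where \eqn{\rho} is the Pearson correlation
#' across cows, penalized by any shift in mean or variance between events.
#' C equals \eqn{\rho} exactly when the two events share mean and variance;
#' it is negative under anticorrelation. Zero variance at either event makes
#' C undefined (`NA`).
#'
#' @param x1,x2 cow-aligned numeric vectors (event 1 and event 2), length >= 3.
#' @return list `c_value`, `pearson_r`, `pearson_p` (two-sided test of rho=0).
#' @export
concordance <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < 3) stop("need at least 3 paired observations")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (v1 == 0 || v2 == 0)
    return(list(c_value = NA_real_, pearson_r = NA_real_, pearson_p = NA_real_))
  ct <- stats::cor.test(x1, x2)
  r <- unname(ct$estimate)
  c_val <- 2 * r * sqrt(v1) * sqrt(v2) / (v1 + v2 + (mean(x1) - mean(x2))^2)
  list(c_value = c_val, pearson_r = r, pearson_p = ct$p.value)
}

#' Stable / unstable classification rule
#'
#' An OTU is stable when its C value exceeds `c_threshold` AND the Pearson
#' correlation is individually significant (p < `p_threshold`); the
#' significance condition can be switched off (`rule = "c_only"`) to use the
#' bare C threshold. Undefined C (zero variance at one event, e.g. an OTU
#' absent at one visit) is classified `undefined-unstable`: absence at one
#' visit is the extreme of instability.
#'
#' @param c_value,pearson_p numeric vectors.
#' @param c_threshold C cut point (default 0.5).
#' @param p_threshold Pearson significance level (default 0.05).
#' @param rule `"conjunctive"` (default) or `"c_only"`.
#' @return character vector `stable` / `unstable` / `undefined-unstable`.
#' @export
classify_stability <- function(c_value, pearson_p, c_threshold = 0.5,
                               p_threshold = 0.05,
                               rule = c("conjunctive", "c_only")) {
  rule <- match.arg(rule)
  ok <- !is.na(c_value)
  pass <- ok & c_value > c_threshold
  if (rule == "conjunctive") pass <- pass & !is.na(pearson_p) & pearson_p < p_threshold
  ifelse(!ok, "undefined-unstable", ifelse(pass, "stable", "unstable"))
}

#' Per-OTU stability assessment across the two sampling events
#'
#' Computes the concordance correlation coefficient, Pearson correlation and
#' its p-value for every OTU from paired cow samples, then applies the
#' stable/unstable rule. Rarefied counts and relative abundances give
#' identical C because both events share the rarefaction depth (C is
#' invariant to common positive scaling).
#'
#' @param x rarefied [otu_table()].
#' @param metadata sample metadata (see [read_sample_metadata()]).
#' @inheritParams classify_stability
#' @return data.frame: `otu_id`, `c_value`, `pearson_r`, `pearson_p`, `label`,
#'   plus the genus-level taxonomy label.
#' @export
assess_stability <- function(x, metadata, c_threshold = 0.5, p_threshold = 0.05,
                             rule = "conjunctive") {
  pr <- pair_samples(x, metadata)
  res <- vapply(seq_len(nrow(pr$x1)), function(i) {
    cc <- concordance(pr$x1[i, ], pr$x2[i, ])
    c(cc$c_value, cc$pearson_r, cc$pearson_p)
  }, numeric(3))
  genus <- ifelse(is.na(x$taxonomy$genus),
                  paste0("unclassified_", deepest_assigned(x$taxonomy)),
                  x$taxonomy$genus)
  out <- data.frame(otu_id = x$otu_ids,
                    c_value = res[1, ], pearson_r = res[2, ], pearson_p = res[3, ],
                    genus = genus, stringsAsFactors = FALSE)
  out$label <- classify_stability(out$c_value, out$pearson_p,
                                  c_threshold, p_threshold, rule)
  out
}

deepest_assigned <- function(tx) {
  apply(tx, 1, function(r) {
    assigned <- which(!is.na(r))
    if (length(assigned)) r[max(assigned)] else "unknown"
  })
}

#' Summarize a stability assessment
#'
#' Bins the C-value distribution into relative frequencies (undefined C
#' excluded from the histogram but counted), reports the stable count and
#' fraction, and tabulates the genus assignments of stable OTUs.
#'
#' @param results data.frame from [assess_stability()].
#' @param breaks histogram breaks over C (default 0.1-wide bins spanning the
#'   observed range, clipped to [-1, 1]).
#' @return list `histogram` (data.frame bin_low, bin_high, fraction),
#'   `n_total`, `n_stable`, `stable_fraction`, `n_undefined`,
#'   `stable_taxonomy` (genus counts, decreasing).
#' @export
stability_summary <- function(results, breaks = seq(-1, 1, by = 0.1)) {
  if (!nrow(results)) stop("no stability results to summarize")
  cv <- results$c_value[!is.na(results$c_value)]
  cv <- pmin(pmax(cv, min(breaks)), max(breaks))
  h <- graphics::hist(cv, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(bin_low = utils::head(h$breaks, -1),
                        bin_high = utils::tail(h$breaks, -1),
                        fraction = if (length(cv)) h$counts / length(cv) else 0)
  stable <- results$label == "stable"
  tab <- sort(table(results$genus[stable]), decreasing = TRUE)
  list(histogram = hist_df,
       n_total = nrow(results),
       n_stable = sum(stable),
       stable_fraction = mean(stable),
       n_undefined = sum(results$label == "undefined-unstable"),
       stable_taxonomy = tab)
}
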