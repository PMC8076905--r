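#' Tukey HSD comparison of taxon abundance across lactation stages
#'
#' One-way comparison of a taxon's relative abundance between lactation
#' stages, with Tukey(-Kramer, for unbalanced groups) adjusted pairwise
#' p-values from the studentized range distribution:
#' q = |mean_a - mean_b| / sqrt((MSE/2)(1/n_a + 1/n_b)), adjusted
#' p = P(Q_{k, N-k} >= q). Stages with fewer than 2 samples are excluded with
#' a warning. Abundances are compared untransformed.
#'
#' @param abundance named list or matrix: rows = taxa, columns = samples, of
#'   relative abundances; a single numeric vector is treated as one taxon.
#' @param stage factor/character vector of stage labels per sample.
#' @return data.frame: `taxon`, `stage_a`, `stage_b`, `diff` (mean_b -
#'   mean_a), `q`, `p_adj`.
#' @export
tukey_stage_comparison <- function(abundance, stage) {
  if (is.null(dim(abundance))) {
    abundance <- matrix(abundance, nrow = 1,
                        dimnames = list("taxon", names(abundance)))
  }
  stage <- as.character(stage)
  tab <- table(stage)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("stage(s) with <2 samples excluded: ", paste(small, collapse = ", "))
    keep <- !stage %in% small
    abundance <- abundance[, keep, drop = FALSE]
    stage <- stage[keep]
  }
  groups <- sort(unique(stage))
  k <- length(groups)
  if (k < 2) stop("need at least 2 stages with >=2 samples")
  n_g <- as.numeric(table(factor(stage, levels = groups)))
  N <- length(stage)
  pairs <- utils::combn(groups, 2)
  out <- vector("list", nrow(abundance))
  for (i in seq_len(nrow(abundance))) {
    y <- abundance[i, ]
    means <- tapply(y, factor(stage, levels = groups), mean)
    mse <- sum(tapply(y, factor(stage, levels = groups),
                      function(v) sum((v - mean(v))^2))) / (N - k)
    rows <- vapply(seq_len(ncol(pairs)), function(pr) {
      a <- match(pairs[1, pr], groups); b <- match(pairs[2, pr], groups)
      d <- unname(means[b] - means[a])
      se <- sqrt((mse / 2) * (1 / n_g[a] + 1 / n_g[b]))
      q <- if (se > 0) abs(d) / se else if (d == 0) 0 else Inf
      p <- if (is.finite(q)) stats::ptukey(q, k, N - k, lower.tail = FALSE) else 0
      c(d, q, p)
    }, numeric(3))
    out[[i]] <- data.frame(taxon = rownames(abundance)[i],
                           stage_a = pairs[1, ], stage_b = pairs[2, ],
                           diff = rows[1, ], q = rows[2, ], p_adj = rows[3, ],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chao1 richness estimator
#'
#' Bias-corrected form S_obs + F1(F1 - 1) / (2(F2 + 1)), where F1 and F2 are
#' the numbers of singleton and doubleton taxa; robust when F2 = 0. The
#' classic (uncorrected) form S_obs + F1^2 / (2 F2) is available via
#' `bias_corrected = FALSE`. Always >= observed richness.
#'
#' @param counts non-negative integer vector of taxon counts in one sample.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return numeric estimate.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (!length(counts) || sum(counts) == 0) stop("empty sample")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Observed species richness
#'
#' @param counts non-negative integer vector of taxon counts in one sample.
#' @return number of taxa with count > 0.
#' @export
observed_species <- function(counts) sum(counts > 0)

#' Per-sample alpha diversity (Chao1 and observed species)
#'
#' @param x rarefied [otu_table()].
#' @return data.frame `sample_id`, `chao1`, `observed_species`.
#' @export
alpha_diversity <- function(x) {
  data.frame(sample_id = x$sample_ids,
             chao1 = apply(x$counts, 2, chao1),
             observed_species = apply(x$counts, 2, observed_species),
             stringsAsFactors = FALSE)
}

#' Paired t-test between the two sampling events
#'
#' Two-sided paired t-test on cow-aligned values (used for alpha diversity
#' between samplings, within a parity class). Zero-variance differences are
#' undefined and flagged rather than reported as a spurious p-value.
#'
#' @param values_t1,values_t2 cow-aligned numeric vectors, length >= 3.
#' @return list `t`, `p_value`, `mean_difference`, `df`, `undefined` (logical).
#' @export
paired_ttest <- function(values_t1, values_t2) {
  if (length(values_t1) != length(values_t2)) stop("vectors must be cow-aligned")
  if (length(values_t1) < 3) stop("need at least 3 pairs")
  d <- values_t2 - values_t1
  if (stats::var(d) == 0)
    return(list(t = NA_real_, p_value = NA_real_, mean_difference = mean(d),
                df = length(d) - 1, undefined = TRUE))
  tt <- stats::t.test(values_t2, values_t1, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(d), df = unname(tt$parameter), undefined = FALSE)
}

#' B/F ratio trend over days in milk
#'
#' Ordinary least-squares fit of the Bacteroidetes/Firmicutes ratio on DIM
#' within one parity class, reporting the per-day slope, its two-sided
#' p-value, and R^2.
#'
#' @param bf_ratios numeric vector of per-sample B/F ratios.
#' @param dims days in milk per sample.
#' @param cohort label stored with the fit (e.g. "primiparous").
#' @return data.frame `cohort`, `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
bf_trend <- function(bf_ratios, dims, cohort = "all") {
  ok <- !is.na(bf_ratios) & !is.na(dims)
  bf_ratios <- bf_ratios[ok]; dims <- dims[ok]
  if (length(bf_ratios) < 3) stop("need at least 3 points")
  if (stats::var(dims) == 0) stop("degenerate DIM: all values equal")
  fit <- stats::lm(bf_ratios ~ dims)
  sm <- summary(fit)
  data.frame(cohort = cohort,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = sm$r.squared,
             p_value = sm$coefficients[2, 4],
             n = length(bf_ratios), stringsAsFactors = FALSE)
}
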