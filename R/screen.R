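#' Per-OTU linear mixed model phenotype screen
#'
#' Each phenotype y is regressed, one OTU at a time, on
#' y = mu + b_i * dim + b_j * ln(rarefied count + offset) + parity + animal + e,
#' where animal is a random intercept (a ~ N(0, sigma^2_B)) absorbing the
#' repeated measures on each cow, and parity enters as a fixed factor with
#' levels capped at 3 (parity >= 3 coded as level 3). Estimation is by
#' restricted maximum likelihood; because thousands of OTUs are fitted against
#' the same response and base design, the fit profiles the REML criterion over
#' the single variance ratio sigma^2_B/sigma^2_e after one eigendecomposition
#' of the animal incidence structure, so each OTU costs one rotation and a 1-D
#' optimization. The p-value for b_j is a Wald t with Satterthwaite
#' denominator degrees of freedom computed from the REML information matrix
#' of the two variance components; when the between-animal variance estimate
#' hits the zero boundary the residual df n_obs - rank(fixed design) is used.
#'
#' @name phenotype_screen
NULL

# eigenstructure of ZZ' for a random intercept per animal; reused across OTUs
reml_rotation <- function(animal) {
  f <- factor(animal)
  Z <- 1 * outer(f, levels(f), "==")
  e <- eigen(tcrossprod(Z), symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0))
}

# REML deviance (up to an additive constant) at log-lambda, on rotated data
reml_deviance <- function(loglam, yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  w <- 1 / (1 + exp(loglam) * d)
  sw <- sqrt(w)
  qrx <- qr(Xt * sw)
  if (qrx$rank < p) return(Inf)
  rss <- sum(qr.resid(qrx, yt * sw)^2)
  (n - p) * log(rss) - sum(log(w)) + 2 * sum(log(abs(diag(qr.R(qrx)))))
}

# Profiled REML fit on pre-rotated data; returns estimates for every fixed
# coefficient plus variance components. Per-coefficient denominator degrees
# of freedom are Satterthwaite approximations from the REML information
# matrix of (sigma2_B, sigma2_e); at the sigma2_B = 0 boundary the residual
# df n - p is used.
reml_fit_rotated <- function(yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  opt <- stats::optimize(reml_deviance, c(-12, 12), yt = yt, Xt = Xt, d = d)
  at_zero <- reml_deviance(-Inf, yt, Xt, d)
  loglam <- if (at_zero <= opt$objective) -Inf else opt$minimum
  lam <- exp(loglam)
  w <- 1 / (1 + lam * d)
  sw <- sqrt(w)
  qrx <- qr(Xt * sw)
  if (qrx$rank < p) stop("singular fixed-effect design")
  beta <- qr.coef(qrx, yt * sw)
  rss <- sum(qr.resid(qrx, yt * sw)^2)
  sigma2_e <- rss / (n - p)
  XtWXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2_e * diag(XtWXinv))
  df <- satterthwaite_df(Xt, d, lam, sigma2_e, XtWXinv, n, p)
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df,
       sigma2_e = sigma2_e, sigma2_B = lam * sigma2_e)
}

# Satterthwaite df per fixed coefficient: df_j = 2 f_j^2 / (g_j' I^-1 g_j)
# with f_j = Var(beta_j), gradient g_j over theta = (sigma2_B, sigma2_e), and
# I the REML information matrix 0.5 tr(P V_k P V_l).
satterthwaite_df <- function(Xt, d, lam, sigma2_e, XtWXinv, n, p) {
  if (!is.finite(lam) || lam <= 0) return(rep(n - p, p))
  v <- sigma2_e * (1 + lam * d)
  Xv <- Xt / v
  Cb <- sigma2_e * XtWXinv                 # Var(beta_hat)
  P <- -Xv %*% Cb %*% t(Xv)
  diag(P) <- diag(P) + 1 / v
  P2 <- P * P                              # P symmetric
  i11 <- 0.5 * sum(P2 * outer(d, d))       # tr(P D P D)
  i12 <- 0.5 * sum(t(P2) * d)              # tr(P D P)
  i22 <- 0.5 * sum(P2)                     # tr(P P)
  info <- matrix(c(i11, i12, i12, i22), 2)
  cov_theta <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov_theta)) return(rep(n - p, p))
  m1 <- crossprod(Xv, d * Xv)              # X'V-1 D V-1 X
  m2 <- crossprod(Xv)                      # X'V-1 V-1 X
  g1 <- colSums(Cb * (m1 %*% Cb))          # diag(C m1 C)
  g2 <- colSums(Cb * (m2 %*% Cb))
  f <- diag(Cb)
  denom <- cov_theta[1, 1] * g1^2 + 2 * cov_theta[1, 2] * g1 * g2 +
    cov_theta[2, 2] * g2^2
  df <- 2 * f^2 / denom
  df[!is.finite(df) | df <= 1] <- n - p
  df
}

# fixed-effect base design: intercept + dim + parity (levels capped at 3);
# constant columns (e.g. parity within a primiparous stratum) are dropped
screen_base_design <- function(dim, parity) {
  pf <- droplevels(factor(pmin(as.integer(parity), 3L), levels = 1:3))
  X <- if (nlevels(pf) >= 2) stats::model.matrix(~ dim + pf)
       else stats::model.matrix(~ dim)  # parity constant within the stratum
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) > 0))
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    stop("collinear fixed-effect terms: ", paste(colnames(X), collapse = ", "))
  }
  X
}

#' Fit the mixed model for a single OTU
#'
#' @param y numeric response (one phenotype, one value per sample).
#' @param dim days in milk per sample.
#' @param parity parity per sample (capped at 3 in the design).
#' @param animal cow identifier per sample (random intercept grouping).
#' @param otu_counts rarefied counts of one OTU per sample.
#' @param offset added inside the log transform, ln(count + offset); default 1
#'   so zero counts are admissible.
#' @return list with `estimate` (b_j), `se`, `t`, `p_value`, `df`,
#'   `sigma2_B`, `sigma2_e`, `fit_status` (`"ok"` or `"non-estimable"` when
#'   the transformed covariate is constant).
#' @export
fit_otu_model <- function(y, dim, parity, animal, otu_counts, offset = 1) {
  stopifnot(offset > 0)
  lx <- log(otu_counts + offset)
  if (stats::var(lx) == 0)
    return(list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                p_value = NA_real_, df = NA_real_, sigma2_B = NA_real_,
                sigma2_e = NA_real_, fit_status = "non-estimable"))
  rot <- reml_rotation(animal)
  X <- cbind(screen_base_design(dim, parity), otu = lx)
  fit <- reml_fit_rotated(drop(crossprod(rot$U, y)), crossprod(rot$U, X), rot$d)
  j <- ncol(X)
  list(estimate = unname(fit$beta[j]), se = unname(fit$se[j]),
       t = unname(fit$t[j]), p_value = unname(fit$p[j]), df = unname(fit$df[j]),
       sigma2_B = fit$sigma2_B, sigma2_e = fit$sigma2_e, fit_status = "ok")
}

#' Bonferroni threshold for the OTU screen
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of OTUs screened (the full table, including
#'   non-estimable OTUs, e.g. 0.05/6363).
#' @return list `threshold` and `neg_log10` (the Manhattan-plot baseline).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  thr <- alpha / n_tests
  list(threshold = thr, neg_log10 = -log10(thr))
}

#' Screen every OTU against every phenotype
#'
#' Runs [fit_otu_model()] for each (OTU, phenotype) pair on a cohort
#' (`all`, `multiparous` or `primiparous` cows; subsetting precedes fitting)
#' and flags Bonferroni significance with the number of OTUs in the table as
#' the denominator. Non-estimable OTUs (constant transformed counts) keep a
#' row with `p_value = NA` and can never be significant, but still count in
#' the denominator.
#'
#' @param x rarefied [otu_table()].
#' @param metadata sample metadata (must cover the table's samples).
#' @param phenotypes phenotype data.frame keyed by `sample_id`.
#' @param phenotype_names which phenotype columns to screen (default all of
#'   milk_yield, ecm, fat_pct, protein_pct, methane present in the table).
#' @param cohort `"all"`, `"multiparous"` or `"primiparous"`.
#' @param alpha family-wise error rate for Bonferroni control.
#' @param offset log-transform offset, see [fit_otu_model()].
#' @return data.frame with one row per (OTU, phenotype): `otu_id`,
#'   `phenotype`, `cohort`, `estimate`, `se`, `p_value`, `neg_log10_p`,
#'   `significant`, `fit_status`; attribute `"bonferroni"` holds the
#'   threshold used.
#' @export
screen_all <- function(x, metadata, phenotypes,
                       phenotype_names = NULL,
                       cohort = c("all", "multiparous", "primiparous"),
                       alpha = 0.05, offset = 1) {
  cohort <- match.arg(cohort)
  md <- metadata
  if (cohort != "all") md <- md[md$parity_class == cohort, , drop = FALSE]
  ids <- intersect(intersect(md$sample_id, x$sample_ids), phenotypes$sample_id)
  if (!length(ids)) stop("empty cohort: no samples shared by table, metadata and phenotypes")
  md <- md[match(ids, md$sample_id), ]
  ph <- phenotypes[match(ids, phenotypes$sample_id), ]
  if (is.null(phenotype_names))
    phenotype_names <- intersect(c("milk_yield", "ecm", "fat_pct", "protein_pct", "methane"),
                                 names(ph))
  counts <- x$counts[, ids, drop = FALSE]
  lx <- log(counts + offset)
  estimable <- apply(lx, 1, stats::var) > 0
  rot <- reml_rotation(md$cow_id)
  Xb <- screen_base_design(md$dim, md$parity)
  Xb_t <- crossprod(rot$U, Xb)
  lx_t <- crossprod(rot$U, t(lx))           # samples x OTUs, rotated
  n_tests <- nrow(counts)
  bon <- bonferroni_threshold(alpha, n_tests)
  out <- vector("list", length(phenotype_names))
  for (k in seq_along(phenotype_names)) {
    yt <- drop(crossprod(rot$U, ph[[phenotype_names[k]]]))
    est <- se <- pv <- rep(NA_real_, n_tests)
    for (i in which(estimable)) {
      fit <- reml_fit_rotated(yt, cbind(Xb_t, otu = lx_t[, i]), rot$d)
      j <- ncol(Xb_t) + 1L
      est[i] <- fit$beta[j]; se[i] <- fit$se[j]; pv[i] <- fit$p[j]
    }
    out[[k]] <- data.frame(
      otu_id = rownames(counts), phenotype = phenotype_names[k], cohort = cohort,
      estimate = est, se = se, p_value = pv, neg_log10_p = -log10(pv),
      significant = !is.na(pv) & pv < bon$threshold,
      fit_status = ifelse(estimable, "ok", "non-estimable"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "bonferroni") <- bon
  res
}
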