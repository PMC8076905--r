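---
title: "Methods: temporal stability and host-phenotype association of the rumen microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal stability and host-phenotype association of the rumen microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rumenstab` implements an analysis pipeline for repeated-measures 16S rRNA
amplicon surveys of the dairy-cow rumen: a cohort of cows is sampled at two
visits during lactation, and the questions are (i) which OTUs keep a stable
abundance within cow across the two visits, (ii) which OTUs associate with
milk and methane phenotypes, (iii) how community composition moves across
lactation stages, and (iv) what the co-occurrence structure of the community
looks like. This vignette documents the statistical model behind each stage,
the synthetic-cohort generator used to validate them, and the numerical and
design decisions baked into the defaults.

## 1. Temporal stability: concordance between visits

For each OTU, the rarefied counts at visit 1 and visit 2 are aligned by cow
(cows lacking either visit are dropped by `pair_samples()`), giving paired
vectors $x_1, x_2$ of length $n$ cows. Agreement is measured by Lin's
concordance correlation coefficient

$$C = \frac{2 \rho \sigma_1 \sigma_2}
          {\sigma_1^2 + \sigma_2^2 + (\mu_1 - \mu_2)^2},$$

with sample (denominator $n-1$) variances and Pearson's $\rho$. Unlike
Pearson's correlation, $C$ penalizes location and scale shifts, so an OTU
that doubles everywhere between visits is *not* concordant. An OTU is
labelled **stable** when $C > 0.5$ *and* the Pearson correlation test has
$p < 0.05$ (the conjunctive rule; `classify_stability(rule = "c_only")`
switches to the threshold alone). When either visit's counts have zero
variance, $C$ is undefined and the OTU is labelled `undefined-unstable`
rather than being given a fabricated value.

Concordance is computed on rarefied counts. Because all samples are rarefied
to a common depth, counts are proportional to relative abundances with a
shared constant, and $C$ is invariant to a common rescaling of both vectors,
so counts versus relative abundances give identical classifications.

## 2. Phenotype screen: per-OTU linear mixed model

Each phenotype $y$ (milk yield, ECM, fat %, protein %, methane) is regressed
one OTU at a time:

$$y_{ic} = \mu + b_d \,\mathrm{DIM}_{ic} + b_j \ln(x_{ic} + 1)
           + \mathrm{parity}_c + a_c + e_{ic},$$

where $x_{ic}$ is the OTU's rarefied count for cow $c$ at visit $i$, parity
is a fixed factor with levels capped at 3, and $a_c \sim N(0, \sigma^2_B)$
is a cow random intercept absorbing the repeated measures. Estimation is by
REML. Because thousands of OTUs are fitted against the same response and
base design, the fit eigendecomposes the cow incidence structure $ZZ'$ once
per cohort, rotates $y$ and $X$, and profiles the REML criterion over the
single variance ratio $\lambda = \sigma^2_B / \sigma^2_e$ with a 1-D
optimization on $\log \lambda \in [-12, 12]$ plus the $\lambda = 0$
boundary. Each OTU then costs about two milliseconds; the unit suite checks
the fit against `lme4::lmer` to six decimals.

The $p$-value for $b_j$ is a Wald $t$ with **Satterthwaite** denominator
degrees of freedom, computed analytically from the REML information matrix
of $(\sigma^2_B, \sigma^2_e)$; at the $\hat\sigma^2_B = 0$ boundary the
residual df $n - p$ is used. A simpler residual-df convention
($n - p - 1$) was measurably anti-conservative in the far tail on null
simulations (extreme $p$-values at roughly 2.5 times their nominal rate),
which matters precisely where Bonferroni thresholds live; Satterthwaite
removes this and agrees with `lmerTest` to about 0.1 % in df.

Family-wise error is controlled by Bonferroni with the **full OTU table**
as denominator, including OTUs that are non-estimable because their
transformed counts are constant (e.g. a threshold of $0.05/6363$ for a
6,363-OTU table). Non-estimable OTUs keep a row with `p_value = NA` and can
never be significant, but they still count in the denominator — dropping
them would quietly relax the threshold. Parity-stratified screens
(`cohort = "multiparous"` / `"primiparous"`) subset the cows before
fitting; within a stratum the parity factor may collapse and is then dropped
from the design.

## 3. Composition across lactation

- **Stages** partition days in milk with half-open bounds: early
  $[1, 50)$, mid $[50, 100)$, late $[100, \infty)$; DIM below 1 is an
  error, not a silent clamp.
- **Stage comparisons** use one-way Tukey HSD (Tukey–Kramer for unbalanced
  groups) on untransformed relative abundances:
  $q = |\bar y_a - \bar y_b| / \sqrt{(\mathrm{MSE}/2)(1/n_a + 1/n_b)}$,
  with adjusted $p = P(Q_{k, N-k} \ge q)$ from `stats::ptukey`. Stages with
  fewer than two samples are excluded with a warning. No blocking on cow is
  applied — the two visits of one cow usually fall in different stages, and
  the procedure matches `TukeyHSD(aov(...))` exactly (checked in the unit
  suite). This slightly understates dependence when a cow contributes two
  samples to comparable stages; a mixed-model contrast would be the
  conservative alternative.
- **Alpha diversity** reports observed species and bias-corrected Chao1,
  $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$, which is defined when no
  doubletons exist and always $\ge S_{obs}$; cross-checked against
  `vegan::estimateR`. Changes between visits are tested with a paired $t$
  within parity class; zero-variance differences are flagged `undefined`
  instead of producing a spurious $p = 1$ from a 0/0 statistic.
- **B/F ratio** (Bacteroidetes / Firmicutes at the phylum level; NA with a
  warning when Firmicutes is zero) is regressed on DIM by OLS within parity
  class, reporting slope, $R^2$ and the slope's $p$-value.

## 4. Co-occurrence: SparCC and keystones

Standard correlations on compositions are spurious, so the network stage
uses SparCC, implemented here from first principles (no R implementation is
assumed):

1. counts are converted to fractions by a Dirichlet posterior draw
   (counts + 1);
2. the variation matrix $t_{ij} = \mathrm{var}\,\log(f_i/f_j)$ is computed
   from the covariance of the log fractions;
3. basis variances $\omega$ solve the SparCC linear system
   $M \omega = \text{row sums of } T$ restricted to included pairs, and
   $\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2 \sqrt{\omega_i
   \omega_j})$, clipped to $[-1, 1]$;
4. strongly correlated pairs ($|\rho| >$ 0.1) are iteratively excluded from
   the basis estimation (up to 10 rounds, never leaving a taxon with fewer
   than 2 partners), re-solving each round;
5. the element-wise median over 20 Dirichlet draws is reported.

Significance comes from permutation: each taxon's row is shuffled
independently, the full estimator is re-run, and
$p = (\#\{|\rho_{perm}| \ge |\rho_{obs}|\} + 1) / (n_{perm} + 1)$, which can
never return an impossible $p = 0$. Edges require $|\rho| > 0.5$ and
$p < 0.05$ (strict inequalities). Keystone genera are ranked by normalized
betweenness centrality via `igraph`; the unit suite verifies betweenness
against exhaustive shortest-path enumeration on random graphs. SparCC
requires at least 4 taxa and 10 samples — below that the basis system is
ill-posed — and its own authors' caveat applies: the estimator assumes the
number of taxa is large and true correlations are sparse.

Genus-level input is produced by `collapse_taxonomy()`, which pools OTUs
unassigned at genus rank into `unclassified_<deepest assigned taxon>`
buckets (conserving totals exactly), and `filter_taxa()` keeps genera with
mean relative abundance above 0.1 %.

## 5. Synthetic cohort generator

`simulate_cohort(sim_config(...))` builds a two-visit cohort with known
ground truth. Defaults mirror the target study design: 60 cows of which
`round(0.45 * n_cows)` are primiparous, visits 122 days apart, first-visit
DIM uniform on [13, 198], 1,000 OTUs, library sizes
$N(10^5, \mathrm{cv}=0.08)$, rarefaction depth 76,000 (70,000 for the
archaeal tag).

Per-OTU latent log abundance for cow $c$ at visit $i$ is

$$z_{ic} = \beta_o + s_o \mathbb{1}[i = 2]
           + \sqrt{\rho_o}\, u_c + \sqrt{1 - \rho_o}\,\varepsilon_{ic},$$

with base effect $\beta_o \sim N(0, 1.5^2)$, cow effect $u_c \sim N(0,1)$,
within-cow persistence $\rho_o = 0.95$ for the designed-stable fraction
(default 5 %) and $0$ otherwise, and a visit shift $s_o \sim N(0, 0.5^2)$
for unstable OTUs. Counts are multinomial draws from the softmax of $z$.
Phenotypes are generated **from the screening model itself** — intercept,
DIM slope, parity effects, cow variance $\sigma^2_B$ and residual
$\sigma^2_e$ per phenotype — plus optional causal terms
$b_j \ln(\text{rarefied count} + 1)$ for chosen OTUs, restrictable to one
parity cohort. A small negative DIM effect on Bacteroidetes in primiparous
cows (−0.0015/day) gives the B/F trend something to find.

What the generator is good for, and what it is not: it produces realistic
marginal sparsity, compositional closure, repeated-measures structure, and
exact null phenotypes, so it supports calibration, power, sign-recovery and
round-trip validation. It does **not** emulate designed inter-taxon
correlation structure (beyond closure), phylogenetic signal, or sequencing
error, so a SparCC network on a default cohort is empty by construction —
network recovery is instead validated on log-normal compositions with an
injected correlated pair. Passing these simulations therefore shows the
statistics are computed correctly and calibrated under the stated model,
not that the model is adequate for any particular real dataset.

## 6. Numerical and design decisions

- All randomness flows through explicit integer seeds (`withr::with_seed`);
  derived seeds stay below $2^{31}$. Reruns are byte-identical.
- Rarefaction is subsampling **without replacement**; samples below depth
  are dropped and reported via the `"dropped"` attribute, not silently
  padded.
- The log transform uses $\ln(x + 1)$ so zero counts are admissible; the
  offset is a parameter of `fit_otu_model()`.
- Undefined statistics (zero-variance concordance, zero-variance paired
  differences, zero-Firmicutes B/F) are reported as NA with an explicit
  flag, never as a numeric that could sort into a ranking.
- Dual-route validation: every hand-authored statistic is tested against an
  independent oracle — concordance vs a direct formula evaluation, the REML
  engine vs `lme4`/`lmerTest`, Tukey vs `TukeyHSD`, Chao1 vs `vegan`,
  betweenness vs brute-force path enumeration, the variation matrix vs
  brute-force log-ratio variances.

## 7. Limitations

- The screen fits one OTU at a time; correlated OTUs produce correlated
  tests and Bonferroni is conservative in that regime.
- Satterthwaite df is an approximation; with 50–60 cows it is accurate, but
  very small cohorts should not rely on far-tail $p$-values.
- SparCC permutation $p$-values are not adjusted for the number of pairs;
  the edge rule combines an effect-size threshold with the raw $p$.
- Tukey stage comparisons ignore the cow pairing across stages (see §3).
- The generator's multinomial sampling understates the overdispersion of
  real amplicon data; calibration results transfer to real data only to the
  extent the mixed model's assumptions hold there.
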