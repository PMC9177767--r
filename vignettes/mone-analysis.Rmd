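---
title: "Statistical models behind monekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models behind monekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monekit)
```

## The mone abstraction

A *mone* ("morphological gene") is one channel of a convolutional network's
global-average-pooled output, summarized per histology slide. Tiles of a
whole-slide image each produce a feature vector; the slide-level value of a
mone is the **median over that slide's tiles**. The median is the only
aggregator monekit offers: it is robust to the minority of tiles that carry
artifacts (pen marks, folds, blur), and for even tile counts we take the
standard sample-median convention of averaging the two central order
statistics. Once aggregated, a cohort is a slides-by-mones matrix that can
be analyzed with the same statistical machinery as a gene-expression
matrix — differential analysis, correlation networks, linear classifiers,
and integration with actual expression data. That analogy is the organizing
idea of this package.

monekit does **not** do any image work: tiling, tissue masking, and network
inference are upstream; the package consumes tile-level feature tables and
slide metadata (patient, cancer type, tumor/normal lesion, frozen/FFPE
preparation, and the vial-level sample key used to match expression
profiles).

## Differential analysis

Two families of per-feature two-class tests are provided.

**Frequentist tests.** Welch's unequal-variance *t* test, the two-sample
Kolmogorov–Smirnov test, and the Wilcoxon rank-sum test, each with
Benjamini–Hochberg adjustment applied across all features within one
(cohort, test) family. The rank-sum test is computed exactly (no ties, both
classes under 20 slides) and by the tie- and continuity-corrected normal
approximation otherwise. Features that are constant in both classes are
reported with p = 1 and a degeneracy flag instead of `NaN`. A caveat worth
knowing: the KS statistic is discrete, so its p-values are conservative at
any finite sample size (we measure null rejection ≈ 0.03–0.04 at nominal
0.05, matching the reference implementations); the *t* and rank-sum tests
are calibrated to within binomial error.

**The optimal Bayesian filter (OBF).** Each feature is scored by the
posterior probability that its class-conditional distributions differ. Data
in a homogeneous block (one class, or all classes pooled) are modeled as
Gaussian with unknown mean and variance under the improper Jeffreys scale
prior $(\sigma^2)^{-3/2}$, with a per-block prior normalization
$c/\sqrt{n_S}$ (the flat location prior referenced at the block's
information scale). The block marginal likelihood is then closed-form:

$$m(S) \;=\; c\,(2\pi)^{-(n-1)/2}\, n^{-1}\, \Gamma(n/2)\,(SS/2)^{-n/2},$$

with $SS$ the centered sum of squares. The non-marker model is one pooled
block (one factor of $c$); the marker model is the product of the two
class blocks (two factors of $c$); the posterior combines them with marker
prior $\pi = 0.5$ and $c = 0.1$. All computation is in the log domain with
`lgamma`. Each marginal is verified in the test suite against 2-D numerical
quadrature of likelihood × prior.

Why this normalization? An improper prior leaves genuine freedom in how its
infinite normalization is referenced, and different conventions shift the
marker/non-marker odds by factors of $\sqrt{n}$. We fixed the convention
**once**, by requiring that the analytic effect-size thresholds reproduce
the published values (below); the $c/\sqrt{n_S}$ reference is the unique
clean convention that does.

**The a(m) statistic and its thresholds.** OBF's evidence is carried by

$$a(m) = \frac{s^2}{s_0^{2w_0}\, s_1^{2w_1}}, \qquad
  w_y = \frac{n_y - 1}{n_0 + n_1 - 2},$$

the ratio of total sample variance to the df-weighted geometric mean of the
class variances (unbiased estimates). It tends to 1 for non-markers.
`am_threshold()` solves for the a(m) at which the posterior reaches a
target, holding total variance at 1 (features standardized — the improper
prior leaves a residual scale dependence, and this reference makes the
threshold well-defined) and assuming equal class variances. At posterior
0.95 with balanced classes this yields a(m) = 1.088 at total n = 200 and
1.159 at total n = 100 — the moderate/strong marker cutoffs. "Sizes 200
and 100" are total cohort sizes split equally; the alternate reading
(class sizes 200 vs 100) does not reproduce the published pair and was
rejected during bring-up.

**Selection rules.** Minimal-risk OBF keeps features with posterior above
$1-\alpha$. FDR-OBF sorts posteriors decreasingly and keeps the largest
prefix whose mean error probability $\overline{1-p}$ is at most $\alpha$,
bounding the sample-conditioned FDR; since $1-p$ is nondecreasing along the
sorted order, the greedy prefix is optimal (tested against exhaustive
search). Posterior sums give moments of the marker count, and per-cancer
posteriors multiply into joint cross-cancer probabilities under
independence.

**Structured OBF.** For cohorts mixing frozen-normal (FN), frozen-tumor
(FT) and FFPE-tumor (PT) slides, four sharing patterns are scored: A (one
distribution), B (frozen vs FFPE), C (tumor vs normal), D (FT vs rest),
with priors (1/2, 1/6, 1/6, 1/6). Each structure's marginal is the product
of its blocks' marginals. A feature whose MAP structure is B with FT and PT
means straddling FN is flagged *FFPE-ineffective*: its apparent
tumor/normal difference is a preparation artifact. Restricting to {A, C}
and merging the tumor groups recovers the plain two-class filter exactly
(a unit test).

### Properizing the prior for calibration tests

The improper prior cannot be sampled, so the FDR-OBF calibration test uses
an exact proper surrogate: $\mu \sim \mathrm{Unif}(-L, L)$,
$\sigma^2 \sim \mathrm{InvGamma}(1/2, b)$, which has the same
$\sigma^2$ power as the improper model and a closed-form block marginal
equal to the package's formula evaluated at $SS + 2b$ with normalization
$(1/2L)\sqrt{b/\pi}$ (and the flat-mean convention shifted by
$\sqrt{n}$). With $L = 100$, $b = 1$ — chosen a priori so that the
uniform truncation mass is negligible — the realized false-discovery
proportion of FDR-OBF stays below $\alpha$, as the theory requires.

## Correlation networks

Covariances are estimated with the **Ledoit–Wolf** shrinkage estimator
(optimal blend of the 1/n sample covariance with a scaled identity; our
implementation matches scikit-learn's to ten digits on fixtures) and
normalized to correlations. Significance uses the **Fisher transform**:
$z = \operatorname{atanh} r$ is treated as normal with variance
$1/(n-3)$; composite nulls $|\rho| \le \rho_0$ (used for the
"highly correlated with a reference mone" analyses, $\rho_0 = 0.5$) are
evaluated at the boundary with the sign of $r$. Differential correlation
between tumor and normal cohorts uses the two-sample statistic
$(z_t - z_n)/\sqrt{1/(n_t-3) + 1/(n_n-3)}$. BH adjustment runs over the
upper-triangle family.

One deliberate choice: the Fisher tests are applied to the **sample**
correlations, while the shrunk matrix is the reported point estimate. The
shrinkage intensity is data-dependent and grows toward 1 when most pairs
are uncorrelated; testing coefficients multiplied by $(1-s)$ against a
null calibrated for the raw estimator would be arbitrarily conservative
(on sparse synthetic structure the planted signal becomes undetectable).
On densely correlated real feature spaces the intensity is small and the
two choices nearly coincide. `use_shrinkage = TRUE` restores testing on
the shrunk values for comparison. Relatedly, the nominal $n$ is used as
the test's effective sample size — shrinkage changes the estimate, not the
test's degrees of freedom — a documented approximation.

Pooled matrices are element-wise means with the diagonal reset to 1;
family preservation is the intersection-over-union of significant pair
sets across the cancers of a family.

## Linear classification

Cross-validation is **Monte Carlo at the patient level**: patients (never
slides) are randomly assigned to train or test, stratified so per-class
test counts track the requested fraction (default 0.25, the conventional
split; the reference pipeline does not state one), 10 repetitions by
default. No patient ever appears on both sides — an invariant asserted in
the test suite on every repetition.

Two linear models are provided. **MLDA** (multi-class linear discriminant
analysis, via `MASS::lda`, with a shrinkage fallback when the within-class
scatter is singular) supplies both class posteriors and a
$(k-1)$-dimensional discriminant projection; the projection can be
embedded in 2-D with t-SNE at perplexity 50 ("number of neighbors 50" maps
onto perplexity, the parameter that sets the effective neighbor count)
using PCA initialization and a fixed seed. **LR-LASSO** is multinomial
logistic regression with an L1 penalty at inverse strength $C = 100$
(`glmnet` with $\lambda = 1/(Cn)$, matching the sum-of-log-losses
parametrization of scikit-learn's `C`; fitted along a warm-started path
from the KKT $\lambda_{\max}$ because coordinate descent cold-started at
one tiny penalty stalls). Coefficients below $10^{-8}$ are reported zero.
AUCs move by less than 0.01 for $C \in [1, 1000]$ on separable cohorts (a
unit test).

Evaluation reports per-class one-versus-rest AUC by the rank statistic
(equal to exhaustive pairwise concordance — tested), macro averages, and
row-normalized confusion matrices. Summing a 38-class model's tumor-class
probabilities yields the universal tumor score; training binary classifiers
per cancer and evaluating across cancers yields the cross-classification
AUC matrix. Clustermap separation is quantified by average-linkage
Euclidean clustering cut at 2, scored by Rand index, adjusted Rand index,
and an AUC from each slide's cluster-level tumor fraction (the AUC
construction is this package's documented choice; the source analyses
print such metrics without defining one).

## Integration with expression

Slides pair to expression profiles by exact vial key (TCGA-style barcodes
truncated after the vial letter; the extraction is configurable for other
naming schemes, and ambiguous keys are an error rather than a first-match).
Genes with zeros in more than half the paired samples or with standard
deviation below 0.25 are removed — "zero counts" are taken as exact zeros
of the log-normalized matrix, since raw counts are not retained. The
mone-gene correlation block comes from Ledoit–Wolf on the stacked
(mones ∥ genes) matrix, with Fisher/BH inference over that block only.
Significant edges form a bipartite graph whose connected components (with
at least 2 mones and 2 genes) are the reported biclusters — components are
the minimal assumption-free clustering of a significance graph.

A correlated mone cluster is summarized by **PC-1** of its member columns,
centered but not scaled (members of one cluster share a scale family;
correlation-PCA is available by standardizing first), with the sign fixed
so the lowest-id member loads non-negatively. Cluster scores correlate
with external covariates by pairwise-complete Pearson with Fisher p-values;
an optional trim rule excludes samples above a stated covariate threshold
(the 3% B-cell outlier rule), and fraction-valued covariates are expected
log-normalized upstream. Gene-set scores (e.g. the immunoglobulin IG
score) are per-sample means over the named genes, requiring full coverage
by default.

## The synthetic cohort generator

The generator emits tile-level tables, metadata, expression, covariates,
and the ground truth needed for recovery tests. Its model is the minimal
hierarchy consistent with the analysis assumptions:

* **slide-level signal**: per feature, standard normal, with marker effects
  (class mean shift δ in sd units, or a target a(m) converted analytically
  through $\delta = \sqrt{(a-1)(n-1)n/(n_0 n_1)}$; optional class variance
  ratio), equicorrelated blocks driven by per-slide latent factors
  ($z = \sqrt{\rho}f + \sqrt{1-\rho}\,\varepsilon$), and structured
  FN/FT/PT group means;
* **tile-level noise**: independent Gaussian (sd 0.3 by default) around
  the slide value, so the median aggregation is exercised nontrivially;
* **expression**: coupled genes built as
  $r\cdot\mathrm{scale}(\text{signal}) + \sqrt{1-r^2}\,\varepsilon$ around
  a baseline, plus independent null genes and low-sd / zero-inflated genes
  that the integration filters must remove;
* **seeding**: one master seed; expression and covariates draw from
  derived sub-seeds so stages regenerate independently.

What it does **not** emulate: heavy-tailed or rectified CNN feature
marginals, batch effects beyond the frozen/FFPE group shifts, or
count-level expression noise. Passing recovery tests therefore demonstrate
correctness of the statistics under their own Gaussian assumptions, not
robustness to real-data pathologies.

Test problem sizes were chosen to make each check sharp yet quick: null
calibration uses 2,000 features at class sizes 20–200; marker recovery 10
planted markers of 1.5 sd among 500 features at 50 slides/class over 25
seeds; correlation-block and bicluster recovery 300 slides/cohort; the
classification cohort is 19 cancers × (tumor, normal) × 40 slides with a
pan-cancer tumor marker, one cancer-specific tumor marker per cancer and
one tissue-identity feature per cancer, each a 4-sd effect — the marker
architecture the real cohorts exhibit (pan-cancer markers exist alongside
large cancer-specific signatures). The whole suite runs in about a minute.

## Numerical notes and limitations

* All OBF arithmetic is log-domain; posteriors come from log-sum-exp.
  Degenerate blocks (zero sum of squares) are errors, not silent NaNs.
* `am_threshold` brackets in $a \in (1, 100]$ and polishes to
  $|posterior - target| < 10^{-10}$; it is strictly decreasing in n.
* Top-k ranking breaks p-value ties by larger |statistic|, then feature id,
  so orderings are reproducible.
* Text tables serialize doubles at 17 significant digits (exact
  round-trip); the Feather container round-trips bit-identically.
* The KS test's conservatism and the sample-vs-shrunk inference choice are
  discussed above; both are properties a user comparing against other
  stacks should know.
* Patient-level stratification is exact for class-pure patients; patients
  whose slides span classes (paired tumor/normal designs) are assigned
  once and counted against each class, so per-class fractions are then
  approximate.

## A worked example

```{r, eval = FALSE}
cfg <- generator_config(
  n_cancers = 2, M = 50,
  slides_per_group = c(tumor_frozen = 50, normal_frozen = 50),
  markers = data.frame(feature = 0, cancer = "all", delta = 2),
  blocks = list(list(features = 1:5, rho = 0.7, cancers = "all")),
  genes = list(n_null = 100,
               coupled = data.frame(target_type = "factor",
                                    target = rep(1, 6), r = 0.7),
               n_lowsd = 5, n_zero = 5),
  seed = 1)
cohort <- generate_cohort(cfg)
mones <- aggregate_tiles(cohort$tiles, cohort$meta)

diff <- run_tests(mones, mones$meta$lesion)
obf <- obf_scan(mones, mones$meta$lesion)
select_fdr_obf(obf$posterior, 0.05)

cp <- correlated_pairs(shrinkage_correlation(mones), alpha = 0.05)
expr <- generate_expression(cohort$truth, cohort$meta, cfg)
mg <- mone_gene_correlation(mones, filter_genes(expr), alpha = 0.05)
extract_bicluster(mg, alpha = 0.05)
```
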