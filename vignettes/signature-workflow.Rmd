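---
title: "Building chemotherapy response signatures from labeled expression cohorts"
author: "chemosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building chemotherapy response signatures from labeled expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosig)
```

## The problem

High-grade serous ovarian cancer is treated with surgery plus platinum-based
chemotherapy, and patients divide into responders (R; platinum-sensitive,
platinum-free interval of six months or more) and nonresponders (NR;
platinum-resistant). Pre-treatment transcriptomes of the tumor immune
microenvironment carry information about which outcome to expect, and the
practical goal is a small gene panel whose expression, summarized by a
classifier, predicts nonresponse before chemotherapy begins.

`chemosig` implements the full development workflow for such a panel:

1. **Differential expression and markers.** R-vs-NR differential expression
   by the two-sided Wilcoxon rank sum test with Bonferroni correction, and
   one-vs-rest cluster markers gated by detection fraction (`min_pct`,
   default 0.1) and fold change (`logfc_threshold`, default 0.25 on
   `avg_log2FC`, the log2 ratio of de-logged group means with a pseudocount
   of one).
2. **Gene-set screening.** Each ordered DE gene list (top 500 genes,
   ordered by absolute log fold change) is tested for over-representation
   against a gene-set collection (hypergeometric, BH-adjusted); the top 10
   significantly enriched sets are each evaluated as a classifier panel,
   and a list is called predictive when at least half of its top sets reach
   a significant classification AUC. Sets with fewer than three genes in
   the cohort are excluded, matching the classifier's minimum panel size.
3. **Single-sample scoring and enrichment.** GSVA-style activity scores
   localize a candidate signature to cell subpopulations and dichotomize
   cohorts for survival analysis; preranked GSEA refines a signature to its
   response-associated leading edge.
4. **Nearest-centroid classification.** A continuous prediction score per
   sample, z-standardized and calibrated to a nonresponse probability.
5. **Recursive elimination.** Backward search over the candidate panel
   maximizing classification AUC, yielding the final signature.
6. **Prognostic screening.** Univariate Cox regression per gene and
   Kaplan-Meier comparison of median-split signature scores.

## The classifier

For a panel of genes $G$ and training cohort $X$ (log-normalized
expression), each gene is standardized by its training mean and standard
deviation; zero-variance genes are dropped, and at least three usable genes
are required. Class centroids $c_R$ and $c_{NR}$ are the standardized class
means. The default continuous score of a sample $z$ is

$$ s(z) = \mathrm{cor}(z, c_{NR}) - \mathrm{cor}(z, c_R), $$

z-standardized against the training score distribution, so that higher
scores always mean nonresponse. A two-parameter logistic regression of the
training labels on the z-scores converts scores into nonresponse
probabilities; prediction on new data always reuses the training gene
scaling, score scaling, and calibration (no re-standardization on test
data).

Pearson correlation makes the score invariant to sample-wise location and
scale over the panel, which is robust across platforms. Its known blind
spot is a panel whose genes all shift in the same direction by the same
amount: centering across panel genes removes exactly that common shift. For
such panels the `method = "euclidean"` variant (difference of mean squared
distances to the two centroids, linear in the profile) preserves the shift;
both variants satisfy the same contracts and are serialized with the model.

Evaluation reports the AUC (Mann-Whitney with ties counted one half), a
p-value from Welch's t-test comparing the class-wise score distributions,
and sensitivity/specificity at the Youden-optimal threshold with Wilson 95%
intervals. The threshold rule is recorded in the result because no single
operating point is canonical.

## The recursive elimination

Starting from the assembled candidate panel (union of significant gene
sets, intersected with per-subtype fold-change gates and the cohort's
genes, ordered lexicographically), each cycle evaluates all $k$ panels
obtainable by removing one gene and keeps the best by AUC; the search stops
at three genes, the classifier's minimum. Per-cycle evaluation counts are
audited in the trace: with $p$ starting genes the search performs
$p(p+1)/2 - 5$ classifier evaluations (the full panel once, then $k$ per
cycle).

Three deliberate choices:

* **Tie-breaking within a cycle** (equal AUCs within $10^{-9}$): remove the
  lexicographically last gene. Any rule is arbitrary here; a deterministic
  one makes runs reproducible across platforms.
* **Selection across cycles**: the panel with the global maximum AUC. When
  several cycles tie within $10^{-9}$ — which in practice happens when the
  training AUC saturates at 1 — the earliest (largest) tied panel is
  selected. Once the criterion is saturated, further removals are decided
  only by the tie-break and carry no evidence, so continuing to shrink the
  panel amounts to unguided pruning that discards informative genes; the
  first attainment is the conservative stop. Smaller panels inside the
  plateau remain available through `size_override`, which mirrors the
  common practice of hand-picking a panel size from a near-flat AUC
  plateau.
* **Evaluation cohort**: by default each subpanel is scored by
  resubstitution on the training cohort, which is the protocol under which
  published per-cycle AUCs of this kind are reported. Resubstitution
  inflates the apparent AUC of the selected panel; for honest
  generalization `holdout_fraction` splits the cohort once (stratified,
  deterministic under `split_seed`), fits centroids on one part and scores
  subpanels on the other. The final signature model is always refit on the
  full cohort.

A subpanel whose classifier cannot be fit (for example, fewer than three
usable genes after dropping zero-variance rows) scores an AUC of 0 and is
logged, so one degenerate gene cannot abort the search.

## Single-sample scores and enrichment

`gsva_scores()` follows the rank-based recipe: a gene-wise cumulative
density across samples (Gaussian kernel, bandwidth $sd/4$, the default; or
the empirical CDF), cross-gene ranks within each sample, the symmetric rank
statistic $|p/2 - r|$, and a weighted Kolmogorov-Smirnov random walk
($\tau = 1$) whose score is the maximum positive plus the maximum negative
deviation. Two invariance regimes follow from the kernel choice and are
worth being precise about: the ECDF kernel is exactly invariant under any
monotone per-gene transformation (it sees only ranks), while the Gaussian
kernel is exactly invariant only under affine per-gene maps (its bandwidth
scales with the data) and approximately invariant otherwise. The Gaussian
kernel remains the default because it is the convention of the reference
implementations of this score; use `kcdf = "ecdf"` when exact rank
invariance matters.

`gsea_preranked()` computes the weighted Kolmogorov-Smirnov enrichment
score against a ranked gene list with a sign-stratified gene-label
permutation null (preranked input has no phenotype to permute), normalizes
by the mean same-sign permuted magnitude, and BH-adjusts across sets. The
extremum is the larger of the maximum and minimum running-sum deviations;
exact ties (within $10^{-12}$, where accumulation order could otherwise
decide) resolve to the depletion side. The leading edge — set members at or
before the peak (at or after it, for depletion) — is the refined panel
returned by `refine_panel_leading_edge()` when the enrichment is
significant in the requested direction. Leading-edge membership is the
pinned interpretation of "screened for enrichment"; the alternative (all
members with positive contribution) is nearly identical for strongly
enriched sets and less standard.

## Survival screening

`univariate_cox_screen()` fits one proportional-hazards model per gene
(Breslow tie handling — adequate for continuous simulated times and the
simplest well-defined choice) and retains genes significant at `alpha`
with the hazard ratio on the requested side of one (risk, HR > 1, or
protective, HR < 1). `km_median_split()` dichotomizes at the median score
(ties to the low group), estimates Kaplan-Meier curves, and compares groups
by the log-rank test. Cox coefficients are equivariant under affine
rescaling of the covariate: the per-unit hazard ratio scales accordingly
while significance is unchanged.

## The synthetic cohorts

The generator draws log-scale expression directly as Gaussian noise around
a baseline — the downstream pipeline consumes log-normalized values, so
simulating counts would add machinery without exercising any additional
code path. Defaults are fixed once to emulate the study conditions: a
two-class cohort of 50 responders and 38 nonresponders (the shape of the
cohort such signatures are evaluated on), 2,000 genes, 20 planted signature
genes shifted by `effect_size_delta = 1` (in units of `noise_sd = 1`) in
nonresponders, baseline log-expression 2. Survival times are exponential
with hazard `0.03/month * exp(beta * score)` — a median of roughly two
years at score zero, realistic for progression-free survival in this
disease — with `beta = 1` per unit of the true panel score and independent
administrative censoring of 30% of subjects at a uniform fraction of their
event time.

A planted gene's single-sample discrimination has the closed form
$\mathrm{AUC} = \Phi(\delta / (\sigma\sqrt{2}))$, which anchors the
effect-size calibration: at $\delta = 2$, $\sigma = 1$ the empirical AUC at
500 samples per class lands within 0.03 of $\Phi(\sqrt 2) \approx 0.921$.
All randomness flows from a single integer seed through per-stage
sub-seeds (stable hashes of stage names), so identical configurations
reproduce cohorts bit for bit and enlarging one stage never perturbs
another. `replicate = 2` draws an independent cohort from the *same
population* — same planted genes, fresh samples and survival — which is
what validating a frozen model on an independent cohort means.

What the generator does **not** emulate: count noise and library-size
variation, batch effects, gene-gene correlation beyond the planted shifts,
doublets, and cluster structure beyond mean-shifted marker blocks. Tests
passing on these cohorts therefore demonstrate the correctness of the
procedures — recovery of planted signal, calibration of null behavior —
not the biological performance of any particular signature on real data.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 300, n_samples_R = 50, n_samples_NR = 38,
                         n_signal_genes = 15, effect_size_delta = 1.5,
                         seed = 42)
train <- simulate_bulk_cohort(cfg)

de <- de_between_conditions(train$expression, train$phenotype, "NR", "R")
panel0 <- head(de$gene[order(de$p_value)], 30)

fit <- build_signature(panel0, train$expression, train$phenotype)
fit

validation <- simulate_bulk_cohort(cfg, replicate = 2)
evaluate_centroid(fit$model, validation$expression, validation$phenotype)
```

The problem sizes used throughout the test suite and the acceptance script
(cohorts of 200-2,000 genes, up to 200 samples per class, 100-2,000
permutations or replicates) were chosen so that every stochastic check has
comfortable resolution while the whole suite runs in well under a minute
per file.

## Known limitations

* The centroid classifier's correlation score degrades on small
  homogeneous-shift panels (see above); the Euclidean variant covers that
  regime.
* Resubstitution AUCs from the elimination are optimistically biased;
  treat `selected_auc` as a search criterion, not a performance estimate,
  and validate frozen models on independent cohorts (or use
  `holdout_fraction`).
* GSVA scores here implement the Gaussian/ECDF rank recipe for
  log-expression; the Poisson-kernel variant for raw counts is out of
  scope.
* The Wilcoxon implementation switches from exact enumeration to the
  tie-corrected normal approximation at a combined sample size of 12; at
  that boundary the two paths can differ by up to about 0.07 in absolute
  p-value (no continuity correction is applied, by design), which is
  immaterial downstream because all screening decisions happen far from
  the switch or at far smaller p-values.
* Multivariate Cox modeling is a thin convenience wrapper over the
  standard fitter, provided for independence checks of a signature against
  clinical covariates.
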