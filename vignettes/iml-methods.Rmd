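---
title: "Integrated machine-learning gene weighting: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated machine-learning gene weighting: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imldiag)
```

## Overview

`imldiag` mines diagnostic genes from two-class expression cohorts by
aggregating feature importance across six classifiers instead of trusting
any single one. This vignette is the package's account of the science:
the statistical models at each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
the numerical choices, and the known limitations.

## The overall-weight statistic

Each base learner $m$ assigns gene $g$ a raw weight $w_{m,g}$ in its own
units — a penalised regression coefficient, an SVM primal-vector entry, a
Gini impurity decrease, a CART importance, a boosting relative influence,
or a network importance. These units are not comparable, so each model's
column is normalised by its own maximum absolute entry and the gene's
overall weight is

$$\mathrm{overall}(g) \;=\; \sum_{m=1}^{6}
  \frac{|w_{m,g}|}{\max_{g'} |w_{m,g'}|} \;\in\; [0, 6].$$

Absolute values make signed coefficients (lasso, SVM, network) and
non-negative importances (forest, tree, boosting) combine consistently;
raw signs are kept in the raw view for reporting. A gene that tops every
model scores 6; a gene every model ignores scores 0. Candidates require
`overall > 1` (strict), i.e. the gene must carry, summed over six models,
at least the equivalent of one model's maximum weight. A model whose
weights are all zero (e.g. a pruned-away tree) contributes zero to every
gene rather than dividing by zero, with a warning.

Normalisation is idempotent, bounded, and equivariant under gene
permutations; these are tested as properties.

## Stage models and their assumptions

**Duplicate collapsing.** Identifiers appearing on several rows (multiple
probes per gene) are collapsed to their per-sample arithmetic mean, in
first-occurrence order; the operation is idempotent.

**Batch adjustment** (`combat_adjust`) implements the standard parametric
empirical-Bayes location/scale model: per (batch, gene) an additive
effect $\gamma$ with a normal prior and a multiplicative effect
$\delta^2$ with an inverse-gamma prior, hyperparameters estimated by
method of moments on gene-wise estimates, shrunk by iterated conditional
means (tolerance $10^{-4}$), then back-transformed. The class label is
included in the standardisation design by default (`protect_class =
TRUE`): the case/control contrast is then not absorbed into the batch
model, which matters exactly when the trait of interest is unevenly
distributed across studies. Both modes are exposed because public
study descriptions often omit this detail. Two caveats are documented
rather than hidden: (i) a single-batch matrix is returned unchanged by
construction, since shrinkage of $\delta^2$ would otherwise perturb data
that need no adjustment; (ii) the per-gene pooled mean is *not* exactly
preserved by this family of methods — shrinkage pulls batch effects
toward their unweighted mean, so size-weighted sums are slightly nonzero
(observed shifts are a few hundredths on a log2 scale, identical to the
reference implementation's behaviour).

**Train/test assignment** is by whole batch (study), never by random
sample split: cross-study generalisation is the claim being tested, and
sample-wise splits would leak batch structure. The default pipeline uses
two batches in a 2:1 sample ratio, the ratio implied by assigning the
large cohort to training and the smaller ones to testing.

**Differential expression.** Per-gene moderated t-statistics: the pooled
two-sample variance $s^2_g$ (with $d$ residual df) is modelled as scaled
inverse-$\chi^2$ with prior df $d_0$ and prior variance $s_0^2$;
posterior variance $s^2_{post} = (d_0 s_0^2 + d s^2_g)/(d_0+d)$, statistic
$\mathrm{logFC}/\sqrt{s^2_{post}(1/n_1+1/n_2)}$ on $d_0 + d$ df.
Hyperparameters come from the closed-form method of moments on log
variances, inverting the trigamma function by Newton iteration (tolerance
$10^{-8}$, 50 iterations). If the moment estimate is inestimable the
prior df falls back to 0 (ordinary t); a homoscedastic cohort drives
$d_0 \to \infty$ (full shrinkage), which is the correct limit. The DEG
filter is strict on both sides — $|\mathrm{logFC}| > 0.7$ and BH-FDR
$< 0.05$ — so boundary genes are excluded; logFC is case minus control on
the log2 scale. BH adjustment delegates to `p.adjust` and is verified
against a brute-force step-up oracle.

**The six learners** follow fixed tuning rules (see `iml_control()`):

| model | tuning | per-gene weight |
|---|---|---|
| lasso | 100-point auto-scaled $\lambda$ grid, 10-fold misclassification CV, fit at $\lambda_{min}$ | coefficients |
| SVM (linear) | cost $\in \{1,\dots,20\}$ by 10-fold CV | primal vector $\sum_i \alpha_i y_i x_i$ |
| random forest | tree count $\in 1..700$ at minimum OOB error | mean Gini decrease |
| CART | fixed $cp = 0.001$ | variable importance, 0 for unused genes |
| boosting | 200 trees, shrinkage 0.001, 90 % row subsampling, logistic (Bernoulli) loss, depth 5 | gain-based relative influence, averaged over six submodels each trained without one stratified fold |
| neural net | three hidden layers (16, 8, 4), sigmoid, SSE objective | Garson importance |

All stochastic components (fold assignment, forests, boosting row
subsampling, network initialisation) are driven by one explicit seed;
identical calls give byte-identical fits, which is tested.

Two extraction rules were genuinely open and decided here. The network's
per-gene weight uses Garson-style importance — the row sums of
$|W_1||W_2||W_3||W_4|$, normalised to sum 1 — because it is
deterministic, architecture-agnostic and standard; a simpler
first-layer-magnitude strategy is exposed as an alternative
(`nn_importance = "first_layer"`). The boosting weight averages the
per-fold relative influence across the six submodels (symmetric in the
folds); the full-data model is kept for prediction.

The network itself is implemented in the package — a fully connected
sigmoid multilayer perceptron trained by BFGS on the sum-of-squared-error
objective — because the three-hidden-layer architecture is part of the
workflow contract. A small L2 term ($10^{-4}$) keeps the separable-data
optimum finite; with default sizes the objective remains SSE-dominated.
Hidden sizes are configurable; (16, 8, 4) is a tapering default sized for
tens of input genes.

**Validation.** Candidates must still differentiate the classes in the
held-out cohort: a two-sided Wilcoxon rank-sum test per gene at
$\alpha = 0.05$ (the test is a parameter; "no differentiation" is not
otherwise defined). Genes whose test-set values are fully tied have no
defined rank-sum p and are excluded. Diagnostic value is the
Mann–Whitney AUC — the probability a random case exceeds a random
control, ties counted half — reported orientation-free
($\max(A, 1-A)$, direction recorded) since biomarkers can be
diagnostic in either direction. The ROC staircase is built by a
descending threshold sweep; its trapezoidal area equals the pair-count
AUC to $10^{-9}$ including under ties, and the two routes are
cross-checked on random fixtures. qPCR support uses the
$2^{-\Delta C_t}$ form against a reference gene per sample, with a
$\Delta\Delta C_t$ calibrator mode.

**Immune correlation.** Cell-type fractions are estimated per sample by
non-negative least squares of the bulk profile on a signature matrix,
renormalised to the simplex (the RMSE of each fit is kept). A linear
ν-SVR mode (ν ∈ {0.25, 0.5, 0.75}, lowest-RMSE fit kept, negative
coefficients clipped) mirrors support-vector deconvolution estimators.
NNLS is the default: deterministic, dependency-light, and exact for
noiseless mixtures of linearly independent signatures. Gene–fraction
association uses Spearman's ρ (Pearson on midranks) with the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; an exact
small-sample p-value is available for $n \le 10$ without ties.

## The synthetic-data generator

Public case/control expression studies are integrated from several array
series; the generator (`cohort_config`/`generate_cohort`) emulates the
statistical structure that pipeline consumes, with known truth:

* baseline per-gene means $\mu_g \sim N(7, 2)$ on the log2 scale,
  resembling summarised microarray intensities (real arrays motivate the
  scale; no claim is made about their exact intensity law);
* a chosen number of planted genes whose case mean shifts by a signed
  log2 fold change drawn uniformly from a stated range, 70 % upregulated
  by default (matching the up/down imbalance typical of the motivating
  AMI contrast);
* additive per-(batch, gene) offsets $N(0, \sigma_{batch})$; a
  multiplicative noise-scale option exists to stress the variance half of
  the batch adjustment;
* i.i.d. $N(0, \sigma)$ residuals, $\sigma = 1$ by default;
* duplicated identifiers emitted as extra rows with independent noise
  around the same signal, to exercise average-collapsing;
* immune mixtures $S f + \varepsilon$ with flat-Dirichlet simplex
  fractions and a synthetic marker-block signature matrix standing in for
  published signatures (which are external artifacts).

Everything is a pure function of the configuration including its seed.
What the generator does **not** emulate — and what passing tests
therefore do not show about real data: probe-level artefacts and
platform-specific normalisation, heavy-tailed or intensity-dependent
noise, correlated gene modules, class-confounded batches, and RNA-seq
count distributions. Results on synthetic cohorts certify the machinery
(recovery, calibration, determinism), not clinical performance.

Default problem sizes used by the test suite follow the package's
standard study design: cohorts of 2,000 genes with 40 planted DE genes,
60/60 training and 30/30 held-out samples across two batches, five seeds
for replicated claims. These sizes give planted effects
($|\mathrm{logFC}| \ge 1.2$ at $\sigma = 1$, $n = 60$/group) detection
power near 1 while keeping full runs to seconds.

## Numerical choices and degenerate inputs

* Strict inequalities at every threshold (DEG filter, candidate cutoff,
  rank-sum filter), so boundary values are excluded.
* Zero-variance genes pass through batch adjustment unadjusted with a
  warning (dropping them would misalign gene sets across stages).
* All-zero weight columns contribute zero with a warning (no 0/0).
* Constant vectors give Spearman ρ = NA with p = 1, flagged.
* EB solver tolerances: $10^{-4}$ (batch shrinkage fixed point),
  $10^{-8}$ (trigamma inversion); ROC/AUC agreement asserted at
  $10^{-9}$.
* Ties: midranks throughout (AUC, Spearman); ROC thresholds sweep unique
  values so tied scores produce diagonal segments whose trapezoids match
  the half-credit pair count.
* Fold assignment is stratified by class; fold counts are capped so each
  fold keeps at least three observations on small fixtures.

## Known limitations

* Accuracies and AUCs printed by published studies on their original
  array cohorts are not reproducible without those arrays; the package
  reproduces printed weight tables exactly and certifies the rest of the
  machinery on synthetic cohorts with planted truth.
* At realistic noise ($\sigma = 1$) a gene planted at logFC 2.0 has
  population AUC $\Phi(2/\sqrt2) \approx 0.92$; individual-gene AUC
  estimates at $n = 30$/group therefore scatter below 0.9 regularly, and
  replicated claims are made about the mean over strong genes, not each
  gene.
* The forest's tree count is chosen at the first OOB-error minimum in
  1..700; OOB error is noisy for very small tree counts, so the choice
  can be small on easy problems. This mirrors the stated tuning rule.
* Nonparametric batch adjustment, paired designs, covariates beyond
  class, and count-based (RNA-seq) models are out of scope.
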