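---
title: "Multi-view kernel k-means subtyping and survival-based evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view kernel k-means subtyping and survival-based evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvkkm)
```

## The problem

Neuroblastoma cohorts are profiled on several expression platforms at once —
typically two differently normalized RNA-seq quantifications and a microarray —
and the clinical question is whether these *views*, integrated rather than
analyzed one at a time, reveal patient subtypes with genuinely different
prognosis. Two properties of such cohorts shape every methodological choice in
this package: the views are highly correlated but not redundant, and the
survival outcome is heavily right-censored (more than 80% of patients have no
observed event).

`mvkkm` implements the full analysis path: multi-view kernel k-means (MVKKM)
subtyping with learned kernel weights, internal-validity model selection,
survival-based evaluation of candidate stratifications, and a supervised
cross-cohort endpoint-prediction protocol — together with a synthetic-cohort
generator so that every stage is testable without access to the original
cohorts.

## The clustering model

Each view is mapped to a Gram matrix with the RBF kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$. Rather than committing to one
bandwidth, a bank of six kernels per view is built over the grid
$\gamma \in \{2^{-14}, \dots, 2^{-19}\}$ (`default_gammas()`). The bank is
combined into a composite kernel

$$\tilde K = \sum_v w_v^{\,p}\, K^{(v)}, \qquad w_v \ge 0,\ \sum_v w_v = 1,$$

and the algorithm alternates (i) kernel k-means on $\tilde K$ and (ii) a
re-weighting of the kernels. The within-cluster distortion of kernel $v$ under
assignment $C$ is

$$D_v = \sum_{c \in C} \Big[ \sum_{i \in c} K^{(v)}_{ii}
      - \tfrac{1}{|c|} \sum_{i, j \in c} K^{(v)}_{ij} \Big],$$

and with the assignment fixed, minimizing $\sum_v w_v^p D_v$ over the simplex
has the closed-form KKT solution $w_v \propto D_v^{-1/(p-1)}$. The composite
distortion is therefore non-increasing across full iterations, which the test
suite asserts over a hundred seeded runs. Kernels that cluster poorly (high
distortion) lose weight; with several kernels per view, per-view contributions
are read off as sums of kernel weights (`aggregate_view_weights()`).

Decisions that the formulation leaves open, and what this package does:

* **Weight update.** The update is not unique folklore — it is the exact
  minimizer of the stated objective; the implementation is verified against an
  exhaustive simplex grid search at step $10^{-3}$.
* **Per-kernel vs per-view weights.** Weights are learned per kernel and
  aggregated per view; this matches reporting per-view weight sums while
  letting each bandwidth find its own relevance.
* **`p = 1` is rejected.** At `p = 1` the simplex minimizer is winner-take-all
  (all weight on the lowest-distortion kernel), which defeats integration; the
  supported range is `p > 1` with the conventional grid `{1.5, 2, 2.5}` and
  default 1.5.
* **Zero distortion.** A kernel with zero within-cluster distortion receives
  all the weight (split uniformly among ties) as the limit of the closed form;
  the case is flagged as degenerate.
* **Empty clusters.** A batch assignment pass can empty a cluster; the sample
  farthest from its own centroid in composite-kernel feature space is moved
  into the empty cluster, deterministically.
* **Initialization and restarts.** Uniform weights plus seeded uniform-random
  labels; 30 restarts by default, lowest final objective wins. Assignment ties
  break toward the lowest cluster index, making runs reproducible bit-for-bit
  under a fixed seed.
* **Convergence.** Labels stable *and* relative objective change below `tol`
  (default $10^{-8}$), capped at `max_iter` (default 100).
* **No feature standardization before the kernel** by default: the method is
  applied to the log2 matrices as distributed. `build_kernel_bank()` exposes a
  `standardize` switch for data whose scales differ across genes.

## Model selection

The number of clusters is chosen by `select_k()`: per restart, MVKKM is fitted
for each candidate `k` and scored by mean silhouette (maximize), Dunn index
(maximize) and connectivity (minimize); the three rankings are combined by
weighted rank aggregation and the restart votes for the top candidate; the
final `k` is the mode of the votes.

* **Metric space.** All indices are computed on the kernel-induced distance
  $d(i,j) = \sqrt{K_{ii} + K_{jj} - 2K_{ij}}$ of the fit's own final composite
  kernel — the geometry the clustering actually optimized. The silhouette of a
  singleton cluster member is 0 by convention.
* **Rank aggregation.** The consensus ordering minimizes the weighted Spearman
  footrule distance to the input rankings. Because candidate lists here have at
  most a handful of entries, the optimum is found by exact enumeration of
  permutations (capped at 8 candidates) instead of a stochastic search:
  deterministic, and provably at least as good as every input ranking. Index
  importance weights default to equal and are exposed in the interface.
* **Tie rules.** Modal ties break toward the smaller `k` (parsimony);
  `select_p()` maximizes mean silhouette over its grid and breaks ties toward
  the smaller `p`.
* **Connectivity neighborhood** `L = 10`, the common default for this index.

## Survival-based evaluation

A candidate stratification is judged by how well it explains censored
survival, with the machinery of the package's evaluation tables:

* **Kaplan–Meier and log-rank** delegate to the `survival` package
  (`survfit` / `survdiff`) behind a stable interface.
* **Firth-penalized Cox.** With >80% censoring and small subgroups, monotone
  likelihood (complete separation) is a real risk, and the unpenalized partial
  likelihood then has no finite maximizer. `cox_firth_fit()` maximizes
  $\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta)$ (a Jeffreys-prior
  penalty) by Newton–Raphson on the modified score with step-halving, Breslow
  handling of ties. Standard errors come from the inverse information at the
  optimum; confidence intervals are Wald intervals on the log hazard ratio.
  Profile-penalized-likelihood intervals — the default of some Firth
  implementations — are out of scope, a documented source of divergence from
  analyses that use them. Model BIC is $-2\,\ell^* + m \ln n$ computed at the
  penalized optimum (the package reports which log-likelihood entered the
  formula, since the convention is ambiguous in the literature).
* **AFT with censoring imputation.** `aft_fit_imputed()` regresses log-time on
  the covariates, initializing censored rows at their censoring times and
  repeatedly replacing them with the conditional mean of the fitted normal
  truncated below at the censoring time,
  $\mu_i + \sigma\,\phi(z_i)/(1 - \Phi(z_i))$, until the imputations move less
  than $10^{-6}$. Imputed times never fall below their censoring times. The
  inverse Mills ratio uses the log-scale form with an asymptotic tail
  expansion, so deep-tail censoring does not overflow.
* **Scoring.** `censored_rmse()` works on the log scale (survival times span
  orders of magnitude); censored rows are penalized only when the prediction
  falls below the known survival lower bound. `harrell_c()` counts
  concordant comparable pairs (shorter time must be an event; tied risks
  count one half; tied times are not orderable and are skipped).
  `cv_evaluate()` runs 10-fold cross-validation ten times with folds
  stratified by the event indicator — without stratification, event-free folds
  are likely at 80% censoring — using the negative predicted log-time as the
  risk score.
* **Covariate coding** in `compare_stratifications()`: cluster membership via
  reference-cell indicators, `age` numeric, `stage` as an ordinal integer.
  For `k > 2` the summary row reports the cluster indicator with the smallest
  Wald p (each fit retains all per-covariate statistics). The literature
  high-risk/low-risk labels are always appended as the baseline row. Samples
  missing `age` or `stage` are dropped with a logged count.

## Supervised cross-cohort protocol

`cross_cohort_predict()` harmonizes genes between cohorts (exact identifier
intersection, one canonical sorted order — no symbol-alias resolution),
applies the same context filter to both (all patients, high-risk only, or
MYCN-non-amplified only), tunes a linear SVM on the training cohort, and
reports AUROC and balanced accuracy on the test cohort.

Tuning is nested: inside each of five inner folds, the top 1000 genes are
ranked by one-way ANOVA F on that fold's training part only — feature
selection never sees held-out samples — and the cost `C` and the class-weight
mode (uniform vs inversely proportional to class frequency) are chosen by
inner accuracy, ties toward the smaller `C` and uniform weights. The printed
cost grids in this literature sometimes lose minus signs in typesetting;
`default_C_grid()` therefore reads the leading powers of ten as negative
exponents (making the grid monotone), with the literal positive-exponent
reading available via `literal = TRUE`. The SVM itself is delegated to
`e1071::svm`; the protocol around it — ranking, nesting, tuning, transfer — is
the package's own surface. AUROC is the Mann–Whitney rank-sum probability with
ties counted one half; balanced accuracy thresholds the decision value at 0.

## The synthetic cohort generator

`simulate_cohort()` produces the study-shaped inputs every test runs on:

* **Views.** Planted labels are drawn from the configured proportions; each
  informative view adds cluster-specific mean shifts on its informative genes
  to i.i.d. Gaussian noise on a log2-like baseline (gene means
  $\mathcal N(7, 4)$). Cluster centers are drawn
  $\mathcal N(0, (\text{effect\_size} \times \text{noise\_sd})^2)$ per cluster
  and gene, so `effect_size` is the SD of between-cluster offsets in noise-SD
  units. Views are correlated only through the shared labels; residual
  cross-view correlation is not modeled.
* **Shared signatures.** The center draw has its own `signal_seed`: two
  cohorts with equal view specs and `signal_seed` but different `seed` carry
  the same molecular signature over independent patients, which is exactly the
  cross-cohort transfer setting.
* **Uninformative views** default to noise variance-matched to an informative
  view's marginal variance
  ($\sigma^2 + \tfrac{m_\text{inf}}{m}\,\text{effect}^2$): a real
  uninformative dataset still carries full biological variance, it is merely
  unaligned with the subtypes. This matters: a noise view with *less* total
  variance than the informative views would be downweighted for the wrong
  reason.
* **Survival.** Event times are exponential with cluster-specific hazards
  (defaults 0.0002 vs 0.001 per day, a fivefold contrast); censoring times are
  exponential with the rate calibrated by bisection so the expected censored
  fraction hits the target (default 0.8, matching the heavy censoring of the
  emulated cohorts).
* **Clinical table.** Binary OS/EFS endpoints are the event indicator with
  symmetric flip noise (EFS gets the higher rate, so the EFS label is less
  unbalanced than OS, as in the real cohorts); the high-risk flag is the
  planted cluster with 10% flips; MYCN status correlates with the flag and has
  a little missingness; age and stage are weakly cluster-linked. EFS times are
  a crude scaled copy of OS times — adequate for exercising interfaces, not
  for quantitative EFS conclusions.
* **What passing tests do not show.** The generator emulates *structure*
  (correlated views, heavy censoring, unbalanced endpoints), not platform
  realism: no negative-binomial counts, no probe effects, no batch structure,
  no aCGH segmentation. Recovery results on these cohorts demonstrate that the
  machinery is correct, not that real cohorts separate this cleanly.

Default sizes used by the reproduction script (`scripts/acceptance.R`): the
unsupervised arm runs the full default cohort (498 patients, three views of
2000 genes, 10 restarts, `k` candidates 2–5); the supervised arm uses two
cohorts of 300 patients with 5000 genes and a shared 50-gene signature at 1.5
SD. These sizes keep a complete run in the tens of seconds while preserving
every qualitative contrast of interest.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 11)
cohort <- simulate_cohort(cfg)
bank <- build_kernel_bank(cohort)

fit <- mvkkm_fit(bank, mvkkm_config(k = 2, p = 1.5, n_restarts = 10, seed = 11))
aggregate_view_weights(fit, bank)

surv <- survival_data(cohort$clinical$os_time, cohort$clinical$os_event)
logrank_test(surv, fit$labels)
compare_stratifications(list(mvkkm = fit$labels), cohort$clinical, surv,
                        repeats = 3, seed = 11)
```

## Known limitations

* Wald rather than profile-penalized confidence intervals for the Firth-Cox
  hazard ratios.
* Exact rank aggregation caps the candidate list at 8 (ample for `k` in 2–6,
  the intended range).
* `harrell_c()` is the plain pair-counting estimator; no Uno-type IPCW
  correction under heavy censoring.
* The generator's EFS endpoint is a noisy derivative of OS, not an independent
  event process.
* Gene matching across cohorts is by exact identifier only.
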