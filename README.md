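# mvkkm

Integrative subtyping of multi-platform gene-expression cohorts with
**multi-view kernel k-means**, and survival-based evaluation of the
stratifications it discovers. Built for the neuroblastoma setting — several
correlated expression views (RNA-seq under two normalizations, microarray,
optionally aCGH) on one patient set, binary OS/EFS endpoints, and survival
outcomes that are more than 80% right-censored — but the machinery is generic.

## What it computes

**Clustering.** Each view enters as a bank of RBF kernels
`K(x,y) = exp(-γ‖x−y‖²)` over six bandwidths `γ ∈ {2⁻¹⁴, …, 2⁻¹⁹}`, combined
into the composite kernel

```
K̃ = Σ_v w_v^p K^(v),   w on the simplex, p > 1
```

MVKKM alternates kernel k-means on `K̃` with a closed-form re-weighting
`w_v ∝ D_v^(−1/(p−1))`, where `D_v` is kernel `v`'s within-cluster distortion —
so kernels (and views) that cluster poorly lose influence. The number of
clusters is chosen by aggregating silhouette, Dunn and connectivity rankings
with an exact weighted-footrule consensus, voting across restarts.

**Evaluation.** Candidate stratifications are compared by Kaplan–Meier /
log-rank, Firth-penalized Cox regression (finite hazard-ratio estimates even
under the complete separation that heavy censoring invites), BIC
(`−2 loglik + m ln n`), and accelerated failure time models with iterative
truncated-normal imputation of censored times, scored by censoring-adjusted
rmse and Harrell's c-index under 10×10 stratified cross-validation.

**Supervised arm.** A cross-cohort endpoint-prediction protocol: genes
harmonized by exact-identifier intersection, ANOVA-F ranking of the top 1000
genes inside each fold, a nested-CV-tuned linear SVM (cost grid and balanced
class weights), evaluated by AUROC and balanced accuracy, with all / high-risk
/ MYCN-non-amplified contexts.

**Synthetic cohorts.** `simulate_cohort()` generates multi-view cohorts with
planted subtypes, cluster-linked exponential survival with censoring
calibrated to a target fraction, unbalanced binary endpoints, and optional
pure-noise views — every claim in the test suite is exercised on these.

## Worked example

```r
library(mvkkm)

cohort <- simulate_cohort(synthetic_config(seed = 1))   # 498 patients, 3 views
bank   <- build_kernel_bank(cohort)                     # 18 RBF kernels
fit    <- mvkkm_fit(bank, mvkkm_config(k = 2, p = 1.5, n_restarts = 10, seed = 1))
fit
#> MVKKMResult: k = 2, p = 1.50, objective = 1.88358 (converged)
#> cluster sizes: 168, 330
#> view weights:
#> rnaseq-mav rnaseq-rpm microarray
#>     0.3338     0.3332     0.3329

surv <- survival_data(cohort$clinical$os_time, cohort$clinical$os_event)
logrank_test(surv, fit$labels)$p
#> [1] 7.647953e-18

compare_stratifications(list(mvkkm = fit$labels), cohort$clinical, surv, seed = 1)
#>                 model k        hr    ci_low   ci_high       wald_p       bic      rmse   c_index
#>                 mvkkm 2 0.1861956 0.1152771 0.3007432 6.346167e-12  986.3676 0.8470708 0.6728830
#>  High Risk / Low Risk 2 3.3981639 2.1842226 5.2867863 5.808305e-08 1005.1438 0.8645913 0.6842937
```

The discovered two-cluster stratification separates survival (log-rank
p ≈ 8e-18), its hazard ratio is far from 1, and its Cox model has a lower
(better) BIC than the literature high-risk/low-risk grouping — the qualitative
pattern the method is designed to surface. The three views receive nearly
uniform learned weights, as expected for strongly correlated expression views.

See `vignettes/mvkkm-methods.Rmd` for the model, all tunable parameters, the
numerical choices, and what the synthetic cohorts do and do not emulate.

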