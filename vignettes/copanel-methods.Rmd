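---
title: "Models and methods behind copanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind copanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

copanel analyses two-scale ordinal symptom panels measured at three waves:
the 7-item anxiety screener (GAD-7) and the 9-item depression screener
(PHQ-9), each item scored 0–3, with baseline covariates collected once.
This vignette is the package's own account of the models it fits, the
defaults it chooses where the methodology leaves choices open, and what its
synthetic-data generator does and does not emulate.

## Data model, scoring, binarization

A panel is wide: one row per subject, item columns `<item>_t<wave>`
(`gad1..gad7`, `phq1..phq9`; waves 1–3) plus covariates. The design is
complete-case: subjects missing any item response are dropped at read time
with a reported count; no imputation is attempted. Three derived views feed
the analyses:

* **Scale totals** (0–21 for anxiety, 0–27 for depression) with a clinical
  flag at total ≥ 7, the screeners' conventional cutoff (`score_panel()`,
  `cutoff` tunable).
* **Mean scores** (total / number of items, 0–3), the common scale the
  growth models use so the two screeners are comparable despite different
  lengths.
* **Binary presence** (0 = absent, 1–3 = present) per item
  (`binarize()`), the representation the lagged networks are estimated on.

Prevalence trends across waves are tested with a Pearson chi-square on the
waves × (flagged, not flagged) table under homogeneity, treating waves as
independent samples; the effect size reported alongside is the contingency
coefficient eta = sqrt(chi-square / N_total) with N_total the grand total of
that table. Both definitions were chosen because they are the ones that
reproduce published descriptive statistics of this design from their
underlying counts; a paired (McNemar-type) trend test would be a different
statistic and is out of scope. Comorbidity rates are conditional
proportions: among subjects above the depression cutoff at wave t, the share
above the anxiety cutoff at wave s ≥ t.

## Parallel-process latent growth (PP-LGCM)

For subject i let y_i stack the six wave-level mean scores (anxiety then
depression, waves 1–3). The parallel-process linear growth model is

y_i ~ MVN(Λμ, ΛΨΛᵀ + Θ),

with Λ block-diagonal per process, loadings fixed at 1 for intercepts and
(0, 1, 2) for slopes, μ the four growth-factor means, Ψ a free 4 × 4
growth-factor covariance and Θ diagonal residual variances. Time scores are
equally spaced (0, 1, 2): with three waves a linear form is the natural
choice and the calendar spacing of the waves is not part of the model.

Estimation is maximum likelihood on the sample moments: Ψ is parameterized
by its Cholesky factor (so it stays positive semidefinite; a near-zero
diagonal triggers a boundary warning), Θ by log standard deviations, and μ
is profiled out by generalized least squares, leaving a 16-parameter
optimization solved by `nlminb` with jittered restarts. Fit statistics use
the likelihood-ratio discrepancy against the saturated model
(T = (n−1)·F_ML, df = 27 − 20 = 7) with the independence model
(free means and variances, zero covariances, df₀ = 15) as baseline:
RMSEA = sqrt(max(T−df, 0)/(df(n−1))), CFI = 1 − max(T−df, 0)/max(T₀−df₀,
T−df, 0), TLI analogous (capped at 1). The substantive outputs are the
cross-process correlations of intercepts and slopes derived from Ψ.

Note one honest limitation of the T statistic: when the sample covariance
matrix is (near) singular — for instance fully noiseless toy data — the
saturated log-determinant is unbounded and fit indices lose meaning. Tests
therefore exercise the "saturated recovery" property with a tiny but
estimable residual, where the statistic behaves at chance level.

## Latent-class growth analysis (LCGA)

Class enumeration uses the latent-class growth form: K classes, each with
its own four growth means θ_k, zero within-class growth-factor variance, and
residual variances shared across classes and waves but free per process.
The residual structure is deliberately parsimonious — the methodology this
implements does not state the constraint, and sharing residuals across
classes is the most stable choice for enumeration. With a diagonal
within-class covariance the EM M-step for θ_k is ordinary least squares on
posterior-weighted wave means, so each iteration is a handful of matrix
products; the observed-data log-likelihood is non-decreasing by
construction and asserted in tests.

**Initialization.** Plain k-means starts are not sufficient here, for two
reasons observed directly on this model family. First, the k-means
within-sum-of-squares objective prefers splitting large classes over
dedicating a center to a small distant class — and small chronic/severe
classes of a few percent are exactly what symptom-trajectory cohorts
produce. Second, EM started from centers alone (with uniform class weights
and marginal variances) loses rare classes even when a center is placed on
them: a component seeded at weight 1/K absorbs a third of the cohort in
its first E-step and the center is dragged off the tail. Every start is
therefore a *classify-then-EM* partition: class means from member
profiles, class weights from partition shares, residual variances pooled
within classes. The partition pool mixes (i) *incremental splits* — the
fitted (K−1)-class solution with one class divided in two by 2-means on
its members' standardized growth factors, the single most reliable route
out of merged-class local optima (enumeration reuses the previous fit;
a standalone fit computes it recursively); (ii) k-means on standardized
wave profiles; (iii) k-means on standardized per-subject growth factors
(standardization upweights the slope dimensions that separate rising from
stable classes); (iv) "tail-seeded" partitions pinning one class on the
extreme 2% of trajectories; (v) k-means on raw growth factors; and (vi)
kmeans++-style distance-weighted random partitions. Every candidate gets
a short EM burn-in (30 iterations) and up to four are continued to
convergence (relative log-likelihood change < 1e-7 or 500 iterations),
with class weights and variances carried over so burn-in plus
continuation is one EM trajectory. `n_restarts` scales the pool size.
Classes are reported in ascending order of total intercept
(α_anx + α_dep), which removes label switching.

**Enumeration criteria.** AIC = −2ℓ + 2q, BIC = −2ℓ + q·ln n,
aBIC = −2ℓ + q·ln((n+2)/24), with q = (K−1) + 4K + 2; relative entropy
E_K = 1 + Σᵢₖ p_ik ln p_ik / (n ln K) (1 = crisp, 0 = uninformative,
undefined at K = 1). The K-versus-(K−1) test is the parametric-bootstrap
likelihood ratio test (BLRT): datasets are simulated from the fitted
(K−1)-class model, both models refitted, and
p = (1 + #{LR_b ≥ LR_obs})/(reps + 1). The Lo–Mendell–Rubin approximation
is intentionally not implemented; the BLRT is the enumeration test. A class
whose expected size falls below one subject marks that start degenerate and
the next candidate is used.

## Cross-lagged panel networks (CLPN)

Between waves t and t+1 the network is estimated by 16 nodewise L1-penalized
logistic regressions: presence of symptom j at t+1 on all 16 presences at t,

logit P(X_j^{t+1} = 1 | X^t, c) = b_j + Σᵢ B_ij X_i^t + γ_jᵀ c.

`B[i, j]` is the log-odds edge i → j; the diagonal holds autoregressive
effects; `edge_or()` gives the elementwise exponential (OR = 1 meaning no
association). Choices the methodology leaves open, and the defaults taken:

* **Penalty and λ.** Lasso with 10-fold cross-validation, folds stratified
  by the outcome and fixed by a seed. The default rule is the
  deviance-minimizing λ (`"min"`), which is prediction-optimal and yields
  dense networks of the kind reported for this design. The one-standard-
  error rule (`"1se"`) is the parsimony configuration: CV-min is known to
  overselect, so support-recovery analyses (does an estimated edge exist in
  the generating model?) use `"1se"`. Both are exported; a fixed λ
  (including 0, the unpenalized fit) bypasses CV.
* **Scaling.** Binary symptom predictors enter raw (common 0/1 scale);
  covariates are standardized and unpenalized. glmnet internally rescales
  penalty factors to sum to the variable count, which would silently
  inflate the symptom penalty when covariates are added; `fit_clpn()`
  compensates so a fixed λ always means the same per-symptom penalty.
* **Edges.** An "estimated edge" is a coefficient that survived the
  penalty — nonzero at machine precision; no post-hoc threshold. Density is
  the edge count over the 256 possible directed edges.
* **Centrality.** Out expected influence of node i is the row sum of B
  excluding the diagonal; in-EI the column sum likewise. Both are computed
  on the log-odds scale and exclude autoregressive loops (standard
  practice: "connections" are between-symptom edges). Standardized
  versions are z-scores across the 16 nodes; a node is flagged influential
  when standardized out-EI exceeds 1. Scale and loop-handling are the two
  choices that cannot be cross-checked against published tables without
  raw data, so they are stated prominently here.
* **Degenerate outcomes.** An outcome that is constant — or whose minority
  category has fewer cases than folds — cannot support the regression; its
  column is zero with a warning. Networks need at least 50 subjects.

## Bootstrap accuracy, difference tests, case-dropping stability

`bootstrap_edges()` draws B subject resamples with replacement and refits
the network each time; each edge gets a 95% percentile interval, and two
edges (or two nodes' centralities) differ significantly when the bootstrap
interval of their difference excludes zero, without multiplicity
correction, mirroring the referenced bootstrap methodology. By default
replicates are refitted at the full-sample penalties (`refit = "fixed"`);
rerunning CV inside every replicate (`refit = "cv"`) is available and
folds the penalty-selection variability into the intervals at roughly
tenfold cost.

`case_drop_stability()` implements the correlation-stability coefficient:
for each drop proportion p in 0.05, 0.10, …, 0.75, subsamples of size
⌈(1−p)n⌉ are drawn without replacement, the network refitted, and the raw
(unstandardized — standardizing inside subsamples would mask scale
shrinkage) expected influence correlated with the full-sample values.
"Correlation ≥ 0.7 with 95% certainty" is operationalized as the 5th
percentile of those correlations staying ≥ 0.7, and the CS coefficient is
the largest p such that every proportion up to p passes (first-failure
scan; a subsample with constant centrality counts as a failure). CS ≥ 0.25
is conventionally acceptable, ≥ 0.5 good. The default 250 subsamples per
proportion is a desk-scale choice, configurable upward.

## Replicability of two lagged networks

`compare_networks()` compares, for example, the T1→T2 and T2→T3 networks.
An edge is "present" when its OR differs from 1. Summaries cover the
subsets all / autoregressive / cross-lagged / replicated-in-both, each
split by OR > 1 and OR < 1, with counts, percentages of each network's own
edge count, mean ± SD of OR values, and a Pearson correlation of edge
weights. Which entries enter the correlations is not fixed by the
methodology; the default correlates over the union of the two support sets
within a subset (replicated-in-both is by definition the intersection),
because union support is what makes the published count/percentage
structure reproducible; correlating all 256 entries is available via
`support = "all"`, and log-OR via `scale = "log"`. Correlations over fewer
than 3 entries are reported as undefined. Centrality similarity is the
correlation of the 16 raw in-EI (and out-EI) values with its test p-value.

## The synthetic-data generator

Because the motivating cohort data are not public, every stage is validated
on generated panels with known ground truth.

**Growth-mixture panels** (`simulate_growth_mixture()`): subject i falls in
class k with probability π_k; its latent mean score at wave t is
α_k + β_k·λ_t + u_i + v_i·λ_t + e_it, clipped to [0, 3], with optional
within-class growth factors (u, v) — zero by default, matching the LCGA
form — and wave residual e. Item scores are round(clip(N(m + offset_item,
item_sd), 0, 3)): a discretized clipped normal, chosen because the analyses
consume only sums/means and binary presence, so matching the first two
moments of item responses suffices. It is not an item-response model:
thresholds, discrimination and category curves are not emulated, which is a
stated limitation. Rounding and clipping make item scores biased towards
the interior near the scale ends (bias < 0.02 for latent means in
[0.9, 2.1] at item_sd = 0.6, growing to ~0.2 at the boundary), so exactness
and recovery checks use trajectories away from the boundaries, and the
default three classes emulating a pandemic-era student cohort — low-stable
69.8%, moderate-rising 27.2%, chronic-high 3.0% — place the chronic class
at the top of the bias-free region. Cross-process dependence runs through
class membership by default; optional growth-factor correlations
(intercept–intercept, slope–slope) support the PP-LGCM recovery checks.
Baseline covariates (sex, age 17–24, four binary pandemic-exposure
indicators) are generated with no effect on outcomes unless configured —
matching their role as adjustment variables.

**Lagged binary panels** (`simulate_clpn_panel()`): wave 1 presences are
independent Bernoulli(p0); afterwards
P(X_j^{t+1} = 1 | X^t) = logistic(b_j + Σᵢ W_ij X_i^t), the exact
generative twin of the CLPN estimator, so edge recovery, bootstrap
behavior and stability can be measured against a known W.

Fixed seeds make both generators bit-reproducible; the pipeline derives
per-stage seeds deterministically from one master seed.

## Problem sizes and numerical choices in the shipped checks

The package's validation suite uses: three-class cohorts of n = 5,000 (100
replicates for BIC selection-rate and estimator-bias checks — class-mean
bias is assessed on the replicate average, since a single cohort's 3%
class has only ~150 subjects and a ±0.05 check on one draw would be mostly
sampling noise); n = 10,000 panels for planted-support recovery; B = 250
bootstrap replicates and 20–50 subsamples per proportion for stability
runs; and 200 Monte-Carlo repetitions with 99 bootstrap replicates each
for the BLRT level study at n = 150 (simulated from a fitted one-class
model, i.e. data truly K = 1). EM tolerances are relative 1e-7 (1e-6 in
the BLRT inner loop); glmnet convergence threshold 1e-12 for exactness
checks. These sizes are the package's validation design; all of them are
plain function arguments.

## Known limitations

* LCGA only for enumeration: no within-class growth variances (GMM) and no
  covariates-on-class regression.
* The item model is moment-matching, not IRT; measurement invariance across
  waves is assumed, not tested.
* Lasso intervals for individual edges against zero are not valid and are
  deliberately not reported; bootstrap intervals quantify accuracy, not
  selection.
* The trend test treats waves as independent samples; subjects are in fact
  repeated, so it is a descriptive effect-size device, not an inferential
  claim about within-person change.
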