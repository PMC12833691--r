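---
title: "Measuring and decomposing health opportunity inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing health opportunity inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opineq)
```

## The measurement problem

In Roemer's equality-of-opportunity framework, differences in health
outcomes split into a part driven by *effort* (choices the person controls)
and a part driven by *environment* (circumstances they do not: demographics,
where they live, what healthcare resources surround them, the condition they
arrive in). Only the environment-driven part — *opportunity inequality*
(IOp) — is normatively objectionable and a target for policy.

`opineq` implements the ex-ante parametric approach for inpatient cohorts
with an ordinal discharge outcome. The health determination equation is

$$H_i = f(E_i, \varepsilon_i),$$

where $E_i$ collects the environmental covariates and $\varepsilon_i$
absorbs effort and idiosyncratic noise (effort that is itself shaped by the
environment is deliberately attributed to the environment, so the estimate
is an ex-ante, environment-inclusive one). An environment-only model is
fitted, and its fitted values $\hat H_i$ form a counterfactual "smoothed"
distribution in which everyone with the same circumstances has the same
outcome. Inequality is measured by the mean log deviation

$$\mathrm{MLD}(y) = \frac1n \sum_i \log\frac{\bar y}{y_i},$$

and the two headline statistics are the absolute and relative opportunity
inequality

$$\theta_a = \mathrm{MLD}(\hat H), \qquad
  \theta_r = \frac{\mathrm{MLD}(\hat H)}{\mathrm{MLD}(H)} \in [0, 1].$$

$\theta_r$ is the share of total health inequality attributable to
environment. Values slightly outside $[0,1]$ are possible in finite samples
with flexible smoothers; the package warns and reports them as-is rather
than clipping, because clipping would hide overfitting.

## From ordinal diagnoses to a continuous health variable

The discharge diagnosis is an ordinal four-category variable (1 = cured,
2 = improved, 3 = not cured, 4 = death). `rint_fit()` applies a rank-based
inverse normal transformation (RINT) with the *midpoint convention*

$$z_k = \Phi^{-1}\!\left(F_{k-1} + \tfrac{f_k}{2}\right),$$

where $f_k$ is the sample frequency of category $k$ and $F_{k-1}$ the
cumulative frequency below it. With only four heavily tied categories,
per-rank (Blom-type) offsets are ill-defined; the midpoint convention is the
natural frequency-based analogue and keeps the map monotone. The transformed
score is *reversed* (negated) so larger means healthier, and shifted by a
constant (default `shift = 5`) to make every value strictly positive — the
MLD needs positive values and, because the MLD is scale-invariant but **not**
translation-invariant, the shift is a declared parameter carried in the
result metadata rather than a hidden detail. The `composite` health variant
averages the reversed transformed scores of the primary and all secondary
diagnoses; averaging on the transformed scale (not the raw 1–4 codes) keeps
distances on the latent-health scale, which is where the RINT argument
places them.

Preprocessing mirrors standard administrative-claims practice: patients
under 45 are dropped, diagnosis groups (four-digit ICD-10) with 30 or fewer
cases are dropped, missing values are mean-imputed (leveled codes round the
mean to the nearest valid level so codings stay legal), and total expenses
are winsorized two-sided at the 1st/99th percentiles with
linear-interpolation quantiles. A per-diagnosis *cost-variance* feature —
the within-group variance of winsorized expenses, quantile-binned into five
ordinal codes 0–4 — captures heterogeneity of utilization among patients
with the same diagnosis. The binning rule (patient-weighted quantile bins,
count configurable) is a package convention; only the 0–4 range of the
resulting code is pinned down externally.

## Three environment-only models

* **Linear regression** (`fit_linear`): OLS with intercept; the parametric
  benchmark. Rank deficiency is an error naming the collinear columns.
* **Conditional inference tree** (`fit_cit`): recursive partitioning that
  chooses split variables by *statistical significance*, not impurity, which
  avoids the selection bias of exhaustive-search trees. At each node every
  covariate is tested against the outcome with the standardized linear
  statistic $T_j = \sum_i x_{ij} H_i$, standardized by its exact permutation
  moments; p-values (asymptotic normal by default, Monte-Carlo permutation
  optionally) are Bonferroni-adjusted across the candidates, and the node
  splits only if the smallest adjusted p-value is below `alpha` (default
  0.05). The split point maximizes the absolute standardized two-sample
  statistic over all admissible cutpoints, ties going to the smallest
  cutpoint. Stopping: non-rejection, the depth limit, node smaller than
  `min_node` (default 20), or no cutpoint leaving `min_bucket` (default 7)
  on each side. The node-level statistics run in compiled code; the tests
  verify the split decisions against an exhaustive plain-R oracle.
* **Random forest** (`fit_forest`): bagged depth-limited regression trees
  with `m` random candidate variables per split (default $\lfloor k/3
  \rfloor$), backed by the `ranger` engine with a single seed controlling
  both randomization layers. The ensemble prediction is the arithmetic mean
  of per-tree predictions, and out-of-bag predictions give an unbiased
  generalization-error estimate.

`tune_depth()` grid-searches tree depth (default grid 1–20) with 5-fold
cross-validation on negative MSE, ties to the smallest depth. Two depths
play different roles and the defaults reflect that: test-set MSE is
typically flattest around depth 5–7, but the *fitted-value dispersion* that
$\theta_a$ measures keeps growing with depth, so the pipeline defaults are
depth 6 for the single tree and depth 8 for the forest — the upper end of
the cross-validated optimum for this class of cohort — with tuning available
per run (`tune$enabled`). Model-fit diagnostics (test MSE, $R^2$) are
computed on a stratified 80/20 split; the inequality statistics use
in-sample fitted values on the full analysis sample, which is the
counterfactual-smoothing reading of the ex-ante approach (out-of-sample
smoothing is available by passing explicit fitted values).

## Shapley decomposition of $\theta_a$

The contribution of covariate $j$ is its Shapley value over covariate
coalitions with value function

$$v(S) = \mathrm{MLD}\left(\hat H^{(S)}\right),$$

where $\hat H^{(S)}$ are the fitted values of the model *refit* on subset
$S$ ($v(\varnothing) = 0$: the empty model predicts the grand mean). Exact
mode (`shapley_exact`) enumerates all $2^k$ coalitions; efficiency
($\sum_j \phi_j = \theta_a$), symmetry and the dummy axiom then hold by
construction, and the test suite asserts them. Because the MLD is not
additively separable, small negative contributions are possible; they are
reported as-is. Forest refits inside exact mode reuse one seed and a reduced
tree count (default `B = 100`) — an explicit approximation knob that keeps
$2^{13} = 8192$ refits at desk scale. `shapley_sampled` provides the
unbiased permutation-sampling estimator with per-variable standard errors,
and collapses to exact enumeration when all $k!$ orderings fit the budget.

For tree models the package also implements the fast path: per-observation
additive attributions by the polynomial-time path-dependent tree-SHAP
algorithm ($O(TLD^2)$ instead of $O(2^k)$), in compiled code, satisfying
local accuracy ($\text{base} + \sum_j \phi_{ij} = \hat H_i$) on every row.
Marginal contributions follow the trees' cover proportions, which implicitly
assumes feature independence. How per-prediction attributions become
*inequality* shares is a convention this package declares explicitly
(`surrogate_inequality_shares`): surrogate coalition predictions are defined
additively as $\hat h_i(S) = \text{base} + \sum_{j \in S} \phi_{ij}$, the
coalition value is the MLD of those surrogate predictions, and the Shapley
value over this cheap value function is computed by exact enumeration (no
retraining; a Gray-code sweep reuses work across coalitions). Exact
retraining mode is the reference implementation in all tests; the surrogate
reproduces its ranking with share differences of a few percentage points on
pilot fixtures. In the pipeline the attribution matrix is computed on a
seeded subsample (default 4,000 rows) — the surrogate values are MLDs, which
a few thousand rows estimate closely at a fraction of the traversal cost.

One variable is one player: dummy blocks from a single categorical covariate
enter as one column, and all 13 covariates are always reported (no
truncation of minor contributors).

## Distributional heterogeneity: RIF / UQR

Effects need not be uniform across the health distribution. For
$\tau \in \{0.25, 0.5, 0.75\}$ (configurable), the recentered influence
function of the $\tau$-quantile,

$$\mathrm{RIF}_i = \hat q_\tau + \frac{\tau - \mathbf 1\{H_i \le \hat
q_\tau\}}{\hat f(\hat q_\tau)},$$

is regressed on the environment (unconditional quantile regression, no fixed
effects). $\hat q_\tau$ is the linear-interpolation sample quantile and
$\hat f$ a Gaussian-kernel density estimate at the quantile with Silverman's
rule-of-thumb bandwidth. Per-quantile inequality is computed on the RIF
scale: one common positivity shift across all $\tau$ (so quantiles are
comparable), $\theta_a(\tau) = \mathrm{MLD}$ of the shifted fitted RIF,
$\theta_r(\tau)$ its ratio to the MLD of the shifted actual RIF, and a
per-quantile exact Shapley decomposition over OLS refits (cheap, so full
enumeration is always feasible here). This RIF-MLD convention is the
package's declared construction for per-quantile opportunity inequality; it
is the reading consistent with reporting absolute/relative values alongside
a per-quantile contribution table. A declining $\theta_r(\tau)$ profile is a
*tail effect*: environment binds hardest on patients in poor health.

## The synthetic cohort generator

Real inpatient settlement records are not redistributable, so the package
ships a generator whose ground truth is known, making every downstream stage
testable end to end.

* **Marginals.** The 13 environmental covariates match the descriptive
  statistics of a provincial cardiovascular/cerebrovascular cohort aged 45+:
  age from a truncated normal whose *parent* parameters are solved
  numerically so the truncated distribution itself has mean 66.2 and sd 10.8
  on [45, 87] (plugging the targets into the parent would shrink the sd by
  over 10%); binaries from their Bernoulli means; three-level ordinal codes
  from categorical distributions solved exactly from their printed mean and
  sd; admission condition (1–4) likewise with a fixed rare top level.
* **Clustered macro covariates.** Bed and doctor densities, rail transit and
  old-revolutionary-area status live at the *city* level (default 11 cities)
  and are shared by all patients of a city, mimicking macro statistics
  matched by city code. City resource profiles sit on quantile midpoints of
  the target distributions (so patient-level moments converge), and patient
  allocation weights are chosen so the two city-level binaries hit their
  target means exactly in expectation.
* **Outcome.** A standardized environment index (weights putting surgical
  level, bed and doctor density on top, matching the contribution ranking
  seen in inpatient IOp studies) enters latent severity as
  $h^* = \sqrt{\rho}\,\text{index} + \sqrt{1-\rho}\,\varepsilon$, where
  $\rho$ = `env_share` is the single ground-truth dial. Cutting $h^*$ at
  fixed cutpoints gives the four discharge categories with default
  frequencies (0.35, 0.50, 0.12, 0.03) — a plausible discharge mix, chosen
  here and configurable since no external value pins it down. Secondary
  diagnoses are noisy copies of the latent severity. The default
  `env_share = 0.12` places the cohort's relative IOp in the 7–13% band
  reported for inpatient cohorts of this type. `nonlinearity =
  "interaction"` adds resource-by-severity product terms (the regime where
  tree ensembles should beat OLS); `"threshold"` adds step effects.
* **Ground truth.** `oracle_iop()` computes the true relative IOp by
  Monte-Carlo integration of the closed-form conditional category
  probabilities $P(k \mid \text{index})$ under the same RINT/reversal/shift
  convention as the pipeline — an independent reference against which the
  test suite checks parameter recovery (linear DGP, mean estimate within
  ±15% over 20 replicates at n = 50,000).

What the generator does **not** emulate: the joint dependence of real
covariates (independent by default; a Gaussian copula over the eight
patient-level covariates is available), disease-specific clinical structure,
and any sampling-frame artifacts. Passing tests therefore demonstrate
correctness of the *method* under a controlled DGP, not unbiasedness on any
particular real cohort.

## Numerical conventions and edge cases

* MLD of any non-positive value is an error instructing a shift, never a
  silent adjustment.
* RINT with a single observed category returns $z = 0$ with a
  degenerate-variance warning.
* Zero-variance covariates get p = 1 in the CIT association test.
* Split ties (equal statistics) resolve to the smallest cutpoint; depth-tie
  in tuning resolves to the smallest depth.
* Observations never out-of-bag (tiny forests) are excluded from the OOB
  error with a warning.
* Surrogate predictions that would be non-positive escalate the shift with a
  warning.
* $R^2$ on a constant test outcome is `NaN` with a warning.
* All randomness flows from one root seed through fixed named substreams, so
  a run (including CSV/JSON outputs) is bit-reproducible.

## Problem sizes

The shipped checks run at deliberately desk-scale sizes: the demo pipeline
uses a 20,000-admission cohort; exact Shapley checks run all 8,192
coalitions at n = 5,000 with reduced-size forest refits (20 trees, depth 2);
parameter-recovery uses 20 replicates at n = 50,000; the CIT null
calibration uses 2,000 Monte-Carlo replicates. These sizes were chosen so a
full verification completes on a laptop while keeping Monte-Carlo error well
inside the asserted tolerances.

## A worked run

```{r, eval = FALSE}
library(opineq)

cfg <- default_run_config(n = 20000, seed = 1)
res <- run_opineq(cfg, out_dir = "results")

res$table1   # theta_a, theta_r, total MLD, test MSE/R^2 per model x variant
res$table3   # per-variable Shapley contribution shares (percent)
res$table4   # per-quantile theta_a(tau), theta_r(tau) and shares

# the same stages, step by step
d    <- simulate_patients(do.call(generator_config, cfg$generator))
env  <- build_environment(filter_study_population(d))
rmap <- rint_fit(env$records$primary_dx, levels = 1:4)
H    <- make_health(env$records, "primary", rmap, shift = 5)
q    <- quantile_iop(env$env, H)
autoplot(q)  # theta_r(tau) profile; declining = tail effect
```

## Known limitations

* Exact decomposition retrains $2^k$ models; beyond `exact_limit = 13`
  covariates use sampling or the surrogate.
* The TreeSHAP-style surrogate inherits the feature-independence assumption
  of cover-weighted marginalization; with strongly correlated covariates
  (e.g. bed and doctor density) correlated variables can trade contribution
  mass. Exact retraining mode is the reference when this matters.
* No bootstrap standard errors for $\theta_a/\theta_r$ (a documented
  extension point), and no inequality indices beyond the MLD.
* The RINT places ordinal categories on a latent-normal scale; inter-category
  distances remain approximations to unobservable clinical distances.
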