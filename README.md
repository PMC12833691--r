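# opineq

Ex-ante parametric measurement and Shapley decomposition of **health
opportunity inequality** (IOp) for patient-level records with an ordinal
discharge outcome.

In Roemer's equality-of-opportunity framework, only the part of health
inequality driven by *circumstances beyond a patient's control* — age and
demographics, the density of hospital beds and doctors where they live,
transport access, the condition they arrive in — calls for policy
correction. `opineq` quantifies that part for inpatient cohorts (the
motivating setting is middle-aged and older cardiovascular/cerebrovascular
patients in administrative claims data) and attributes it to individual
environmental variables. It is written for health economists and
epidemiologists working with hospital discharge records.

## The method

The ordinal discharge diagnosis (1 = cured, 2 = improved, 3 = not cured,
4 = death) is mapped to a continuous scale by a rank-based inverse normal
transformation, reversed so larger is healthier, and shifted positive. An
**environment-only** health determination equation

$$H_i = f(E_i, \varepsilon_i)$$

is then fitted three ways — OLS, a conditional inference tree (significance-
based recursive partitioning), and a random forest — and the fitted values
$\hat H_i$ form a counterfactual distribution in which identical
circumstances mean identical health. With the mean log deviation
$\mathrm{MLD}(y) = \tfrac1n\sum_i \log(\bar y / y_i)$,

$$\theta_a = \mathrm{MLD}(\hat H), \qquad
  \theta_r = \theta_a / \mathrm{MLD}(H)$$

are the absolute and relative opportunity inequality; $\theta_r$ is the
share of total health inequality attributable to environment. Each
variable's contribution to $\theta_a$ is its **Shapley value** over
covariate coalitions (value of a coalition = MLD of the model refit on that
subset), computed exactly over all $2^k$ coalitions, by permutation
sampling, or through a fast tree-attribution surrogate (path-dependent
SHAP on the fitted trees, in compiled code). **Unconditional quantile
regression** on the recentered influence function of each quartile, with a
per-quantile Shapley decomposition, shows how the environment's grip varies
across the health distribution.

Because real settlement-platform records are confidential, the package
ships a calibrated synthetic cohort generator (13 environmental covariates
with realistic marginals, city-clustered resource variables, a latent
severity with a configurable environment share) plus `oracle_iop()`, a
Monte-Carlo ground truth against which the whole pipeline's recovery is
tested.

## Worked example

```r
library(opineq)

cfg     <- generator_config(n = 5000, seed = 42)   # env_share = 0.12
cohort  <- simulate_patients(cfg)
analysis <- build_environment(filter_study_population(cohort))
rmap    <- rint_fit(analysis$records$primary_dx, levels = 1:4)
health  <- make_health(analysis$records, "primary", rmap, shift = 5)

model <- fit_linear(analysis$env, health)
tidy(opportunity_inequality(model, health))
#> # A tibble: 1 × 6
#>   family variant total_mld absolute_iop relative_iop shift
#>   <chr>  <chr>       <dbl>        <dbl>        <dbl> <dbl>
#> 1 linear primary    0.0155      0.00135       0.0875     5

shares <- shapley_exact(analysis$env, health, model_recipe("linear"))
head(dplyr::arrange(tibble::as_tibble(shares), dplyr::desc(share)), 5)
#> # A tibble: 5 × 3
#>   variable              phi share
#>   <chr>               <dbl> <dbl>
#> 1 beds_per_1000    0.000271 20.1
#> 2 doctors_per_1000 0.000270 20.0
#> 3 surgical_level   0.000201 14.9
#> 4 old_area         0.000190 14.1
#> 5 rail_transit     0.000122  9.03

oracle_iop(cfg, n_mc = 200000)
#> [1] 0.08447761
```

Reading: total health inequality in this 5,000-admission cohort is
MLD = 0.0155; the environment-smoothed distribution carries
$\theta_a$ = 0.00135 of it, i.e. $\theta_r \approx$ 8.8% of health
inequality is attributable to circumstances — close to the generator's true
share of 8.4% (the `oracle_iop` value for `env_share = 0.12`). Healthcare
accessibility (bed and doctor density, surgical level) tops the
contribution ranking, together accounting for over half of the
environment-driven inequality.

The full pipeline — both health variants, all three model families,
decomposition and quantile analysis, written as CSV report tables — is one
call:

```r
res <- run_opineq(default_run_config(n = 20000, seed = 1), out_dir = "results")
res$table1   # theta_a / theta_r / total MLD / test MSE, R^2 per model
res$table3   # Shapley contribution shares (percent)
res$table4   # per-quantile theta_a(tau), theta_r(tau) + shares
```

A thin command-line wrapper lives at `inst/scripts/opineq.R`
(`Rscript opineq.R simulate|run --config cfg.yaml --seed N --out PATH`).

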