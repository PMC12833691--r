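#' Configure the synthetic inpatient-record generator
#'
#' Builds the configuration of a data-generating process that emulates an
#' administrative inpatient cohort of middle-aged and older cardiovascular /
#' cerebrovascular patients: 13 environmental covariates with realistic
#' marginals, a latent health severity equal to a standardized environment
#' index (weight `sqrt(env_share)`) plus an aggregate effort/noise term
#' (weight `sqrt(1 - env_share)`), and a 4-category ordinal discharge
#' diagnosis obtained by cutting the latent severity at `cutpoints`
#' (1 = cured, 2 = improved, 3 = not cured, 4 = death).
#'
#' Macro covariates (hospital beds and doctors per 1,000 residents, rail
#' transit, old revolutionary area) are drawn at the city level and shared
#' by all patients of a city, mimicking macro statistics matched to patient
#' records by city code. Patient allocation weights across cities are chosen
#' so the patient-level means of the two city-level binaries hit their
#' configured targets.
#'
#' @param n sample size.
#' @param seed integer seed; the same seed yields byte-identical tables.
#' @param env_share fraction in `[0, 1]` of latent-severity variance
#'   attributable to environment. The default 0.12 places the relative
#'   opportunity-inequality share of the cohort in the 7--13% range typical
#'   of inpatient IOp studies.
#' @param nonlinearity `"linear"`, `"interaction"` (adds products of
#'   resource and severity covariates to the environment index) or
#'   `"threshold"` (adds step functions of the resource covariates).
#' @param cutpoints three strictly increasing reals cutting the latent
#'   severity into the four discharge categories. Defaults give category
#'   frequencies (0.35, 0.50, 0.12, 0.03).
#' @param marginals per-covariate distribution targets; see
#'   [default_marginals()].
#' @param n_diagnosis_groups number of four-digit ICD-10 diagnosis groups.
#' @param secondary_dx_rate per-slot probability of a secondary diagnosis
#'   (each patient has up to 3 slots).
#' @param n_cities number of synthetic cities carrying the macro covariates.
#' @param copula optional correlation matrix (Gaussian copula) for the eight
#'   patient-level covariates, in the order age, gender, ethnicity,
#'   marital_status, occupational_risk, surgical_level,
#'   emergency_admission, admission_condition. Default `NULL` draws them
#'   independently.
#'
#' @return A `opineq_config` list.
#' @export
generator_config <- function(n = 20000, seed = 1, env_share = 0.12,
                             nonlinearity = c("linear", "interaction",
                                              "threshold"),
                             cutpoints = qnorm(cumsum(c(0.35, 0.50, 0.12))),
                             marginals = default_marginals(),
                             n_diagnosis_groups = 20,
                             secondary_dx_rate = 0.5,
                             n_cities = 11,
                             copula = NULL) {
  nonlinearity <- match.arg(nonlinearity)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer.", call. = FALSE)
  assert_scalar_prob(env_share, "env_share")
  assert_scalar_prob(secondary_dx_rate, "secondary_dx_rate")
  if (length(cutpoints) != 3L || any(diff(cutpoints) <= 0))
    stop("`cutpoints` must be 3 strictly increasing reals.", call. = FALSE)
  if (!is.null(copula)) {
    if (!is.matrix(copula) || nrow(copula) != 8L || ncol(copula) != 8L ||
        any(abs(copula - t(copula)) > 1e-8))
      stop("`copula` must be a symmetric 8 x 8 correlation matrix.",
           call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 env_share = env_share, nonlinearity = nonlinearity,
                 cutpoints = as.numeric(cutpoints), marginals = marginals,
                 n_diagnosis_groups = as.integer(n_diagnosis_groups),
                 secondary_dx_rate = secondary_dx_rate,
                 n_cities = as.integer(n_cities), copula = copula),
            class = "opineq_config")
}

#' Default marginal targets for the synthetic cohort
#'
#' Marginal moments of the 13 environmental covariates of a provincial
#' inpatient cohort aged 45+: continuous covariates as truncated-normal
#' targets (mean, sd, min, max), binaries as Bernoulli means, ordinal
#' covariates as categorical distributions matching mean and sd.
#'
#' @return A named list of marginal specifications.
#' @export
default_marginals <- function() {
  list(
    age = list(type = "truncnorm", mean = 66.202, sd = 10.769,
               min = 45, max = 87, integer = TRUE),
    gender = list(type = "bernoulli", mean = 0.502),
    ethnicity = list(type = "bernoulli", mean = 0.971),
    marital_status = list(type = "bernoulli", mean = 0.866),
    occupational_risk = list(type = "categorical", levels = 0:2,
                             mean = 0.528, sd = 0.872),
    beds_per_1000 = list(type = "truncnorm", mean = 6.767, sd = 1.348,
                         min = 5.13, max = 10.05, city = TRUE),
    doctors_per_1000 = list(type = "truncnorm", mean = 2.609, sd = 0.643,
                            min = 1.43, max = 3.83, city = TRUE),
    rail_transit = list(type = "bernoulli", mean = 0.11, city = TRUE),
    old_area = list(type = "bernoulli", mean = 0.606, city = TRUE),
    surgical_level = list(type = "categorical", levels = 0:2,
                          mean = 0.789, sd = 0.874),
    emergency_admission = list(type = "bernoulli", mean = 0.2),
    admission_condition = list(type = "categorical4", levels = 1:4,
                               mean = 1.127, sd = 0.466, p_top = 0.002)
  )
}

# Environment-index weights on standardized covariates. Signs encode the
# direction on latent *severity* (higher = worse outcome); magnitudes put
# surgical level, bed density and doctor density at the top of the
# contribution ranking, as observed in inpatient IOp decompositions.
env_index_weights <- function() {
  c(age = 0.30, gender = 0.05, ethnicity = -0.03, marital_status = -0.08,
    occupational_risk = 0.10, beds_per_1000 = -0.45,
    doctors_per_1000 = -0.35, rail_transit = -0.28, old_area = 0.12,
    surgical_level = -0.55, emergency_admission = 0.18,
    admission_condition = 0.35, dx_group_effect = 0.20)
}

# City table: macro covariates on a quantile-balanced resource gradient,
# with patient allocation weights pinned to the target shares of the two
# city-level binaries.
build_city_table <- function(config) {
  m <- config$n_cities
  mg <- config$marginals
  pr <- (seq_len(m) - 0.5) / m
  beds_par <- truncnorm_solve(mg$beds_per_1000$mean, mg$beds_per_1000$sd,
                              mg$beds_per_1000$min, mg$beds_per_1000$max)
  doc_par <- truncnorm_solve(mg$doctors_per_1000$mean, mg$doctors_per_1000$sd,
                             mg$doctors_per_1000$min, mg$doctors_per_1000$max)
  beds <- qtruncnorm(pr, beds_par$mu, beds_par$sigma, beds_par$a, beds_par$b)
  docs <- qtruncnorm(pr, doc_par$mu, doc_par$sigma, doc_par$a, doc_par$b)
  p_rail <- mg$rail_transit$mean
  p_old <- mg$old_area$mean
  rail <- c(rep(0L, m - 1L), 1L)             # metro: the resource-richest city
  n_old <- max(1L, ceiling(0.6 * (m - 1L)))  # old areas: low-resource cities
  old <- c(rep(1L, n_old), rep(0L, m - n_old))
  w <- numeric(m)
  w[m] <- p_rail
  w[seq_len(n_old)] <- p_old / n_old
  rest <- setdiff(seq_len(m - 1L), seq_len(n_old))
  w[rest] <- (1 - p_rail - p_old) / length(rest)
  tibble::tibble(city = seq_len(m), beds_per_1000 = beds,
                 doctors_per_1000 = docs, rail_transit = rail,
                 old_area = old, weight = w)
}

draw_patient_covariates <- function(config, n) {
  mg <- config$marginals
  draw_one <- function(spec, u) {
    switch(spec$type,
      truncnorm = {
        par <- truncnorm_solve(spec$mean, spec$sd, spec$min, spec$max)
        x <- qtruncnorm(u, par$mu, par$sigma, par$a, par$b)
        if (isTRUE(spec$integer)) x <- pmin(spec$max, pmax(spec$min, round(x)))
        x
      },
      bernoulli = as.integer(u < spec$mean),
      categorical = {
        p <- cat3_probs(spec$levels, spec$mean, spec$sd)
        spec$levels[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
      },
      categorical4 = {
        p <- cat4_probs(spec$levels, spec$mean, spec$sd, spec$p_top)
        spec$levels[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
      },
      stop("unknown marginal type"))
  }
  vars <- c("age", "gender", "ethnicity", "marital_status",
            "occupational_risk", "surgical_level", "emergency_admission",
            "admission_condition")
  if (is.null(config$copula)) {
    u <- matrix(runif(n * length(vars)), n, length(vars))
  } else {
    z <- matrix(rnorm(n * length(vars)), n, length(vars)) %*%
      chol(config$copula)
    u <- pnorm(z)
  }
  out <- lapply(seq_along(vars), function(i) draw_one(mg[[vars[i]]], u[, i]))
  names(out) <- vars
  tibble::as_tibble(out)
}

# Core of the DGP: covariates, standardized environment index, latent
# severity and ordinal diagnoses. Shared by simulate_patients() and
# oracle_iop() so both see exactly the same process.
generate_core <- function(config, n, seed) {
  set.seed(seed)
  cities <- build_city_table(config)
  city <- sample.int(config$n_cities, n, replace = TRUE,
                     prob = cities$weight)
  pat <- draw_patient_covariates(config, n)
  G <- config$n_diagnosis_groups
  gamma <- seq(-1, 1, length.out = G)
  gprob <- (1 / seq_len(G)) / sum(1 / seq_len(G))
  grp <- sample.int(G, n, replace = TRUE, prob = gprob)
  icd <- sprintf("I%02d%d", 10L + seq_len(G), seq_len(G) %% 10L)
  expenses <- rlnorm(n,
                     meanlog = 8.5 + 0.3 * gamma[grp] +
                       0.1 * (pat$admission_condition - 1),
                     sdlog = 0.55 + 0.2 * (gamma[grp] + 1) / 2)
  df <- dplyr::bind_cols(pat, cities[city, c("beds_per_1000",
                                             "doctors_per_1000",
                                             "rail_transit", "old_area")])
  df$dx_group_effect <- gamma[grp]
  w <- env_index_weights()
  zs <- function(x) {
    s <- sd(x)
    if (s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  }
  Z <- vapply(names(w), function(v) zs(df[[v]]), numeric(n))
  index <- as.numeric(Z %*% w)
  if (config$nonlinearity == "interaction") {
    index <- index + 0.6 * Z[, "surgical_level"] * Z[, "beds_per_1000"] +
      0.4 * Z[, "doctors_per_1000"] * Z[, "age"]
  } else if (config$nonlinearity == "threshold") {
    index <- index + 0.8 * (Z[, "beds_per_1000"] > 0.5) +
      0.6 * (Z[, "doctors_per_1000"] < -0.5)
  }
  index <- zs(index)
  es <- config$env_share
  noise <- rnorm(n)
  h_star <- sqrt(es) * index + sqrt(1 - es) * noise
  primary <- findInterval(h_star, config$cutpoints) + 1L
  n_sec <- rbinom(n, 3L, config$secondary_dx_rate)
  sec <- character(n)
  has <- which(n_sec > 0L)
  for (i in has) {
    hs <- 0.8 * h_star[i] + 0.6 * rnorm(n_sec[i])
    sec[i] <- paste(findInterval(hs, config$cutpoints) + 1L, collapse = ";")
  }
  records <- tibble::tibble(
    patient_id = seq_len(n), city = city,
    age = df$age, gender = df$gender, ethnicity = df$ethnicity,
    marital_status = df$marital_status,
    occupational_risk = df$occupational_risk,
    beds_per_1000 = df$beds_per_1000,
    doctors_per_1000 = df$doctors_per_1000,
    rail_transit = df$rail_transit, old_area = df$old_area,
    surgical_level = df$surgical_level,
    emergency_admission = df$emergency_admission,
    admission_condition = df$admission_condition,
    total_expenses = expenses, icd10_group = icd[grp],
    primary_dx = primary, secondary_dx = sec)
  list(records = records, index = index, h_star = h_star)
}

#' Simulate a synthetic inpatient cohort
#'
#' Draws a patient-record table from the configured data-generating process.
#' Reproducible: the same configuration (including seed) yields a
#' byte-identical table.
#'
#' @param config a [generator_config()].
#' @return A tibble with one row per admission: demographics, city-level
#'   healthcare-resource covariates, admission covariates, total medical
#'   expenses, four-digit ICD-10 diagnosis group, ordinal primary discharge
#'   diagnosis (1 = cured ... 4 = death) and semicolon-separated secondary
#'   diagnoses (empty string if none).
#' @examples
#' cfg <- generator_config(n = 500, seed = 42)
#' simulate_patients(cfg)
#' @export
simulate_patients <- function(config) {
  stopifnot(inherits(config, "opineq_config"))
  generate_core(config, config$n, substream(config$seed, "generate"))$records
}

#' Monte-Carlo ground-truth relative opportunity inequality
#'
#' Estimates the true relative IOp share of a generator configuration: the
#' MLD of the positively shifted conditional mean of the transformed health
#' outcome given the environment, divided by the MLD of the positively
#' shifted transformed outcome itself. Uses the same rank-based inverse
#' normal transformation (midpoint convention), value reversal and shift as
#' the preprocessing pipeline, and the closed-form conditional category
#' probabilities of the latent-threshold DGP, so it is an independent
#' reference for parameter-recovery checks.
#'
#' @param config a [generator_config()].
#' @param n_mc Monte-Carlo sample size (use at least 1e5).
#' @param shift positivity shift applied to the transformed outcome.
#' @return A single number in `[0, 1]` (up to Monte-Carlo error).
#' @export
oracle_iop <- function(config, n_mc = 200000, shift = 5) {
  stopifnot(inherits(config, "opineq_config"))
  core <- generate_core(config, as.integer(n_mc),
                        substream(config$seed, "oracle"))
  es <- config$env_share
  cut <- config$cutpoints
  cat_obs <- core$records$primary_dx
  f <- tabulate(cat_obs, nbins = 4L) / n_mc
  keep <- f > 0
  zmap <- qnorm(cumsum(f) - f / 2)
  zmap[!keep] <- 0
  t_rev <- -zmap
  if (any(t_rev[keep] + shift <= 0))
    stop("`shift` too small for positivity.", call. = FALSE)
  actual <- t_rev[cat_obs] + shift
  m <- sqrt(es) * core$index
  s <- sqrt(1 - es)
  bounds <- c(-Inf, cut, Inf)
  if (s > 0) {
    P <- vapply(seq_len(4), function(k) {
      pnorm((bounds[k + 1] - m) / s) - pnorm((bounds[k] - m) / s)
    }, numeric(length(m)))
    cond_mean <- as.numeric(P %*% t_rev) + shift
  } else {
    cond_mean <- t_rev[findInterval(m, cut) + 1L] + shift
  }
  mld(cond_mean) / mld(actual)
}

#' @export
print.opineq_config <- function(x, ...) {
  cat("<opineq generator config>\n")
  cat(sprintf("  n = %d, seed = %d, env_share = %.3f, DGP = %s\n",
              x$n, x$seed, x$env_share, x$nonlinearity))
  cat(sprintf("  cutpoints = (%s), %d diagnosis groups, %d cities\n",
              paste(sprintf("%.3f", x$cutpoints), collapse = ", "),
              x$n_diagnosis_groups, x$n_cities))
  invisible(x)
}
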