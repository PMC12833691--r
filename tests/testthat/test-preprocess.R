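test_that("study filter keeps age 45+ and diagnosis groups above 30 cases", {
  rec <- toy_records(sizes = c(10, 30, 31, 100, 2))
  out <- filter_study_population(rec)
  kept <- table(out$icd10_group)
  expect_setequal(names(kept), c("I130", "I140"))
  expect_equal(as.numeric(kept[c("I130", "I140")]), c(31, 100))

  rec$age[1] <- 30
  out2 <- filter_study_population(rec, min_cases = 0)
  expect_equal(nrow(out2), nrow(rec) - 1)

  # all ages eligible and all groups large: identity
  big <- toy_records(sizes = c(50, 60))
  expect_equal(filter_study_population(big), big)
  expect_error(filter_study_population(big, min_age = 200), "empty")
})

test_that("mean imputation fills continuous and leveled columns correctly", {
  df <- tibble::tibble(cont = c(1, NA, 3), bin = c(0, 0, 1))
  out <- impute_means(df)
  expect_equal(out$cont, c(1, 2, 3))
  df2 <- tibble::tibble(bin = c(0, 0, 1, NA))
  expect_equal(impute_means(df2)$bin, c(0, 0, 1, 0))  # 0.25 rounds to level 0
  df3 <- tibble::tibble(ord = c(1, 3, 3, NA))
  # undeclared non-binary column: continuous, raw mean
  expect_equal(impute_means(df3)$ord[4], mean(c(1, 3, 3)))
  # declared leveled: mean 2.33 rounds to the nearest observed level, 3
  expect_equal(impute_means(df3, leveled = "ord")$ord[4], 3)
  expect_identical(impute_means(df), impute_means(impute_means(df)))
  expect_error(impute_means(tibble::tibble(x = c(NA_real_, NA_real_))),
               "fully missing")
})

test_that("winsorization caps at the requested percentiles and is idempotent", {
  x <- as.numeric(1:100)
  w <- winsorize(x, 1, 99)
  expect_equal(min(w), quantile(x, 0.01, names = FALSE))
  expect_equal(max(w), quantile(x, 0.99, names = FALSE))
  expect_equal(w[10:90], x[10:90])
  # idempotent at fixed cap values
  expect_equal(winsorize(w, bounds = attr(w, "bounds")), w)
  expect_equal(winsorize(x, 0, 100), x, ignore_attr = TRUE)  # no-op bounds
  expect_equal(winsorize(rep(3, 10)), rep(3, 10), ignore_attr = TRUE)
})

test_that("RINT maps cumulative-frequency midpoints to normal quantiles", {
  m2 <- rint_fit(rep(1:2, c(50, 50)))
  expect_equal(m2$z, c(-0.6744898, 0.6744898), tolerance = 1e-6)
  m4 <- rint_fit(rep(1:4, c(50, 30, 15, 5)))
  expect_equal(m4$z, c(-0.67449, 0.38532, 1.15035, 1.95996),
               tolerance = 1e-5)
  expect_true(all(diff(m4$z) > 0))
  # symmetric frequencies give z symmetric about 0
  ms <- rint_fit(rep(1:4, c(20, 30, 30, 20)))
  expect_equal(ms$z, -rev(ms$z))
  expect_warning(rint_fit(rep(2L, 10)), "Single observed category")
  # large-sample transformed variable: mean ~ 0, variance < 1 (discreteness)
  set.seed(1)
  x <- sample(1:4, 20000, replace = TRUE, prob = c(.35, .5, .12, .03))
  mm <- rint_fit(x)
  z <- rint_apply(mm, x)
  # skewed discrete mass keeps a small systematic offset from zero
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(var(z), 1)
  expect_gt(var(z), 0.5)
})

test_that("health vectors reverse the transformed scale and respect the shift", {
  m4 <- rint_fit(rep(1:4, c(50, 30, 15, 5)))
  rec <- tibble::tibble(primary_dx = c(1L, 4L), secondary_dx = c("", ""))
  h <- make_health(rec, "primary", m4, shift = 5)
  expect_equal(as.numeric(h[1]), 5 + 0.6744898, tolerance = 1e-6)
  expect_true(all(h > 0))
  expect_equal(attr(h, "shift"), 5)
  # better category => larger health value
  expect_gt(h[1], h[2])
  # composite equals primary when there are no secondary diagnoses
  hc <- make_health(rec, "composite", m4, shift = 5)
  expect_equal(as.numeric(hc), as.numeric(h))
  # composite averages transformed scores of all diagnoses
  rec2 <- tibble::tibble(primary_dx = 1L, secondary_dx = "2;3")
  hc2 <- make_health(rec2, "composite", m4, shift = 5)
  expect_equal(as.numeric(hc2), 5 + mean(-m4$z[c(1, 2, 3)]))
  # shift too small to guarantee positivity
  expect_error(make_health(rec, "primary", m4, shift = 1), "shift")
  # permutation equivariance
  rec3 <- tibble::tibble(primary_dx = c(2L, 1L, 3L), secondary_dx = "")
  expect_equal(as.numeric(make_health(rec3, "primary", m4, 5))[c(2, 1, 3)],
               as.numeric(make_health(rec3[c(2, 1, 3), ], "primary", m4, 5)))
})

test_that("no-missing single-diagnosis pipeline equals -z + shift exactly", {
  rec <- toy_records(sizes = c(60, 80))
  m <- rint_fit(rec$primary_dx, levels = 1:4)
  h <- make_health(rec, "composite", m, shift = 5)
  expect_equal(as.numeric(h), -rint_apply(m, rec$primary_dx) + 5)
})

test_that("cost-variance feature bins group variances into ordinal codes", {
  rec <- tibble::tibble(
    icd10_group = rep(c("A", "B"), each = 50),
    total_expenses = c(rnorm(50, 100, 1), rnorm(50, 100, 10)))
  code <- cost_variance_feature(rec, n_bins = 2)
  expect_equal(unique(code[rec$icd10_group == "A"]), 0)
  expect_equal(unique(code[rec$icd10_group == "B"]), 1)
  # constant costs in every group: variance 0 everywhere, one bin
  rec2 <- tibble::tibble(icd10_group = rep(c("A", "B"), each = 10),
                         total_expenses = rep(7, 20))
  expect_true(all(cost_variance_feature(rec2, n_bins = 5) == 0))
  expect_warning(
    cost_variance_feature(tibble::tibble(icd10_group = c("A", "B", "B"),
                                         total_expenses = c(1, 2, 3))),
    "size 1")
})

test_that("build_environment assembles the 13 analysis covariates", {
  d <- simulate_patients(generator_config(n = 2000, seed = 5))
  d$total_expenses[c(3, 9)] <- NA
  env <- build_environment(d)
  expect_equal(ncol(env$env), 13)
  expect_false(anyNA(env$env))
  expect_true("cost_variance" %in% names(env$env))
  expect_true(all(env$env$cost_variance %in% 0:4))
  expect_equal(env$report$imputed[["total_expenses"]], 2)
})
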