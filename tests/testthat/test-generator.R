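test_that("generator is deterministic and respects configured ranges", {
  cfg <- generator_config(n = 2000, seed = 42)
  d1 <- simulate_patients(cfg)
  d2 <- simulate_patients(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 2000)
  expect_true(all(d1$age >= 45 & d1$age <= 87))
  expect_true(all(d1$primary_dx %in% 1:4))
  expect_true(all(d1$total_expenses >= 0))
  expect_true(all(d1$doctors_per_1000 >= 1.43 & d1$doctors_per_1000 <= 3.83))
  expect_true(all(nchar(d1$icd10_group) == 4))
  d3 <- simulate_patients(generator_config(n = 2000, seed = 43))
  expect_false(identical(d1$age, d3$age))
})

test_that("covariate sample moments match the configured marginals", {
  d <- simulate_patients(generator_config(n = 60000, seed = 7))
  expect_equal(mean(d$age), 66.202, tolerance = 0.02)
  expect_equal(sd(d$age), 10.769, tolerance = 0.05)
  expect_equal(mean(d$gender), 0.502, tolerance = 0.03)
  expect_equal(mean(d$ethnicity), 0.971, tolerance = 0.01)
  expect_equal(mean(d$beds_per_1000), 6.767, tolerance = 0.02)
  expect_equal(mean(d$doctors_per_1000), 2.609, tolerance = 0.02)
  expect_equal(mean(d$rail_transit), 0.11, tolerance = 0.05)
  expect_equal(mean(d$old_area), 0.606, tolerance = 0.02)
  expect_equal(mean(d$occupational_risk), 0.528, tolerance = 0.05)
  expect_equal(sd(d$occupational_risk), 0.872, tolerance = 0.05)
  expect_equal(mean(d$surgical_level), 0.789, tolerance = 0.05)
  expect_equal(mean(d$admission_condition), 1.127, tolerance = 0.02)
  # default cutpoints produce the intended discharge mix
  freq <- as.numeric(table(factor(d$primary_dx, 1:4))) / nrow(d)
  expect_equal(freq, c(0.35, 0.50, 0.12, 0.03), tolerance = 0.1)
})

test_that("without environment signal the outcome is independent of covariates", {
  d <- simulate_patients(generator_config(n = 5000, seed = 3, env_share = 0))
  # association between the strongest configured driver and the outcome
  p <- cit_test(d$surgical_level, as.numeric(d$primary_dx))
  expect_gt(p, 0.01)
  cors <- abs(cor(d$primary_dx, d[, c("age", "beds_per_1000",
                                      "doctors_per_1000", "surgical_level")]))
  expect_true(all(cors < 0.05))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(env_share = 1.2), "env_share")
  expect_error(generator_config(cutpoints = c(1, 1, 2)), "increasing")
  expect_error(generator_config(n = 0), "positive")
  expect_error(generator_config(copula = diag(3)), "8 x 8")
})

test_that("oracle IOp hits the boundary cases and is monotone in env_share", {
  expect_lt(oracle_iop(generator_config(n = 10, seed = 1, env_share = 0),
                       n_mc = 20000), 1e-10)
  expect_equal(oracle_iop(generator_config(n = 10, seed = 1, env_share = 1),
                          n_mc = 20000), 1, tolerance = 1e-10)
  grid <- c(0.05, 0.2, 0.4, 0.6, 0.9)
  vals <- vapply(grid, function(es)
    oracle_iop(generator_config(n = 10, seed = 5, env_share = es),
               n_mc = 40000), numeric(1))
  expect_true(all(diff(vals) > -0.01))  # monotone up to MC error
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("gaussian copula induces the requested covariate dependence", {
  R <- diag(8)
  R[1, 5] <- R[5, 1] <- 0.6  # age with occupational risk
  d <- simulate_patients(generator_config(n = 20000, seed = 9, copula = R))
  expect_gt(cor(d$age, d$occupational_risk), 0.3)
  d0 <- simulate_patients(generator_config(n = 20000, seed = 9))
  expect_lt(abs(cor(d0$age, d0$occupational_risk)), 0.03)
})
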