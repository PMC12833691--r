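test_that("OLS recovers closed-form two-group means and is permutation invariant", {
  E <- data.frame(g = rep(c(0, 1), each = 20))
  H <- ifelse(E$g == 1, 4, 2)
  fit <- fit_linear(E, H)
  expect_equal(unname(fit$coefficients), c(2, 2), tolerance = 1e-12)
  expect_equal(fit$diagnostics$r2, 1)
  expect_equal(fit$diagnostics$mse, 0)
  set.seed(2)
  E2 <- data.frame(a = rnorm(50), b = runif(50))
  H2 <- 1 + 2 * E2$a - E2$b + rnorm(50)
  perm <- sample(50)
  f1 <- fit_linear(E2, H2)
  f2 <- fit_linear(E2[perm, ], H2[perm])
  expect_equal(f1$coefficients, f2$coefficients)
  # rank deficiency names the collinear column
  E3 <- data.frame(a = E2$a, dup = E2$a)
  expect_error(fit_linear(E3, H2), "dup")
})

test_that("association test is calibrated and handles degenerate input", {
  set.seed(5)
  x <- rnorm(100)
  expect_lt(cit_test(x, x), 1e-20)           # identical variable
  expect_equal(cit_test(rep(1, 50), rnorm(50)), 1)  # constant: p = 1
  # p-values uniform under the null: KS-type check on repeated simulation
  p <- replicate(400, cit_test(rnorm(60), rnorm(60)))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
  # Monte-Carlo permutation p-value agrees with asymptotic, deterministically
  set.seed(1)
  x2 <- rnorm(80); y2 <- 0.5 * x2 + rnorm(80)
  p_mc1 <- cit_test(x2, y2, method = "montecarlo", n_perm = 999, seed = 4)
  p_mc2 <- cit_test(x2, y2, method = "montecarlo", n_perm = 999, seed = 4)
  expect_identical(p_mc1, p_mc2)
  expect_equal(p_mc1, cit_test(x2, y2), tolerance = 0.02)
})

test_that("conditional inference tree splits where the oracle says", {
  # threshold DGP: root must split on E1 near 0
  set.seed(7)
  n <- 500
  E <- data.frame(E1 = runif(n, -1, 1), E2 = rnorm(n), E3 = rnorm(n))
  H <- as.numeric(E$E1 > 0) + rnorm(n, 0, 0.1)
  fit <- fit_cit(E, H, max_depth = 1)
  expect_equal(fit$nodes$variable[1], "E1")
  expect_lt(abs(fit$nodes$threshold[1]), 0.05)
  # max_depth = 0: single leaf predicting the grand mean
  fit0 <- fit_cit(E, H, max_depth = 0)
  expect_equal(nrow(fit0$nodes), 1)
  expect_equal(unique(fit0$fitted), mean(H))
  # agreement with the exhaustive plain-R oracle on tiny instances
  for (s in 1:12) {
    set.seed(s)
    n2 <- sample(20:50, 1)
    k <- sample(1:3, 1)
    E2 <- as.data.frame(matrix(rnorm(n2 * k), n2, k))
    H2 <- E2[[1]] * runif(1, 0.5, 2) + rnorm(n2, 0, 0.5)
    orc <- cit_root_oracle(E2, H2)
    fit2 <- fit_cit(E2, H2, max_depth = 1, min_node = 14, min_bucket = 7,
                    alpha = 0.9999)
    if (!is.na(fit2$nodes$variable[1])) {
      expect_equal(match(fit2$nodes$variable[1], colnames(E2)),
                   orc$variable)
      expect_equal(fit2$nodes$threshold[1], orc$point, tolerance = 1e-10)
    }
  }
})

test_that("pure-noise data rarely splits at the nominal level", {
  set.seed(21)
  single_leaf <- replicate(200, {
    E <- as.data.frame(matrix(rnorm(80 * 3), 80, 3))
    fit <- fit_cit(E, rnorm(80), alpha = 0.05)
    nrow(fit$nodes) == 1
  })
  expect_gt(mean(single_leaf), 0.90)
})

test_that("forest predictions are the mean of per-tree predictions", {
  set.seed(3)
  E <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  H <- E$a + 0.5 * E$b + rnorm(300, 0, 0.3)
  fit <- fit_forest(E, H, B = 25, m = 2, max_depth = 4, seed = 9)
  per_tree <- predict(fit, E, per_tree = TRUE)
  expect_equal(rowMeans(per_tree), predict(fit, E), tolerance = 1e-12)
  expect_equal(fit$fitted, predict(fit, E))
  # degenerate ensemble: B = 1, m = k, no resampling = one CART-style tree
  one <- fit_forest(E, H, B = 1, m = 3, max_depth = 3, seed = 1,
                    bootstrap = FALSE, sample_fraction = 1, oob = FALSE)
  pt <- predict(one, E, per_tree = TRUE)
  expect_equal(as.numeric(pt[, 1]), predict(one, E))
  # OOB warning when B is too small for full coverage
  expect_warning(fit_forest(E, H, B = 2, m = 1, max_depth = 2, seed = 2),
                 "out-of-bag")
  # OOB error close to held-out MSE on a fresh sample
  big <- fit_forest(E, H, B = 300, m = 2, max_depth = 4, seed = 4)
  E_new <- data.frame(a = rnorm(2000), b = rnorm(2000), c = rnorm(2000))
  H_new <- E_new$a + 0.5 * E_new$b + rnorm(2000, 0, 0.3)
  test_mse <- evaluate(big, E_new, H_new)$mse
  expect_equal(big$diagnostics$oob_error, test_mse, tolerance = 0.15)
})

test_that("depth tuning picks enough depth and is reproducible", {
  set.seed(8)
  n <- 600
  E <- data.frame(x = runif(n, -1, 1), z = runif(n, -1, 1))
  H <- as.numeric(E$x > 0) + as.numeric(E$z > 0.5) + rnorm(n, 0, 0.15)
  d1 <- tune_depth("cit", E, H, grid = 1:5, folds = 4, seed = 3)
  d2 <- tune_depth("cit", E, H, grid = 1:5, folds = 4, seed = 3)
  expect_identical(as.integer(d1), as.integer(d2))
  expect_gte(as.integer(d1), 2)  # two-way threshold needs two split levels
  expect_s3_class(attr(d1, "cv"), "tbl_df")
})

test_that("test-set diagnostics match hand computation", {
  model <- structure(list(family = "linear", fitted = NULL,
                          coefficients = c(0, 1), terms = "x"),
                     class = c("opineq_linear", "opineq_model"))
  # H = (1, 2, 3), predictions (1, 2, 4)
  out <- evaluate(model, data.frame(x = c(1, 2, 4)), c(1, 2, 3))
  expect_equal(out$mse, 1 / 3)
  expect_equal(out$r2, 0.5)
  expect_warning(ev <- evaluate(model, data.frame(x = c(1, 2)), c(2, 2)),
                 "undefined")
  expect_true(is.nan(ev$r2))
})

test_that("broom-style accessors return tidy tibbles", {
  set.seed(1)
  E <- data.frame(a = rnorm(100), b = rnorm(100))
  H <- E$a + rnorm(100)
  lin <- fit_linear(E, H)
  expect_named(tidy(lin), c("term", "estimate"))
  g <- glance(lin)
  expect_true(all(c("family", "mse", "r2") %in% names(g)))
  rf <- fit_forest(E, H, B = 20, m = 1, max_depth = 3, seed = 1)
  expect_true("importance" %in% names(tidy(rf)))
  ct <- fit_cit(E, H, max_depth = 2)
  expect_true(all(c("variable", "threshold", "mean") %in% names(tidy(ct))))
})
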