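#' Fit the environment-only linear health determination equation
#'
#' Ordinary least squares of the (transformed, shifted) health outcome on
#' the environmental covariates with an intercept. The fitted values form
#' the counterfactual "smoothed" health distribution of the ex-ante
#' parametric approach.
#'
#' @param E data frame of environmental covariates.
#' @param H numeric health outcome.
#' @return A `opineq_linear` / `opineq_model` object.
#' @export
fit_linear <- function(E, H) {
  stopifnot(is.data.frame(E) || is.matrix(E))
  H <- as.numeric(H)
  X <- as.matrix(E)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(H), nrow(X) > ncol(X))
  fit <- lm(H ~ X, model = FALSE)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- sub("^X", "", names(cf)[is.na(cf)])
    stop(sprintf("Rank-deficient design; collinear column(s): %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fv <- as.numeric(fitted(fit))
  names(cf) <- c("(Intercept)", colnames(X))
  structure(list(family = "linear", fitted = fv, coefficients = cf,
                 terms = colnames(X),
                 hyperparameters = list(),
                 diagnostics = list(
                   mse = mean((H - fv)^2),
                   r2 = if (var(H) > 0)
                     1 - sum((H - fv)^2) / sum((H - mean(H))^2)
                   else NA_real_,
                   oob_error = NA_real_)),
            class = c("opineq_linear", "opineq_model"))
}

#' @export
predict.opineq_linear <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$terms, drop = FALSE])
  storage.mode(X) <- "double"
  as.numeric(cbind(1, X) %*% object$coefficients)
}

#' Fit a random regression forest of the health determination equation
#'
#' Two-layer randomization: `B` bootstrap resamples, each growing a
#' depth-limited regression tree that minimizes mean squared error over `m`
#' randomly chosen candidate variables per split. The ensemble prediction is
#' the arithmetic mean of the per-tree predictions; out-of-bag (OOB)
#' predictions average only the trees whose bootstrap excluded the
#' observation, giving an unbiased generalization-error estimate. Backed by
#' the `ranger` engine.
#'
#' @param E data frame of environmental covariates.
#' @param H numeric health outcome.
#' @param B number of trees.
#' @param m candidate variables per split (default `floor(k / 3)`).
#' @param max_depth maximum tree depth; `NULL` grows unpruned trees.
#' @param min_node minimum node size.
#' @param seed seed controlling both randomization layers.
#' @param bootstrap draw bootstrap resamples (`FALSE` with
#'   `sample_fraction = 1` disables resampling: a degenerate ensemble).
#' @param sample_fraction fraction of rows per tree.
#' @param oob compute out-of-bag predictions and error (skip for cheap
#'   coalition refits).
#' @return A `opineq_forest` / `opineq_model` object.
#' @export
fit_forest <- function(E, H, B = 500, m = NULL, max_depth = NULL,
                       min_node = 5, seed = 1, bootstrap = TRUE,
                       sample_fraction = 1, oob = TRUE) {
  stopifnot(is.data.frame(E) || is.matrix(E), B >= 1)
  E <- as.data.frame(E)
  H <- as.numeric(H)
  k <- ncol(E)
  m <- m %||% max(1L, floor(k / 3))
  stopifnot(m >= 1, m <= k)
  rf <- ranger::ranger(x = E, y = H, num.trees = as.integer(B),
                       mtry = as.integer(m),
                       min.node.size = as.integer(min_node),
                       max.depth = if (is.null(max_depth)) 0L
                                   else as.integer(max_depth),
                       replace = isTRUE(bootstrap),
                       sample.fraction = sample_fraction,
                       importance = "impurity", oob.error = isTRUE(oob),
                       num.threads = 1L, seed = as.integer(seed),
                       respect.unordered.factors = FALSE)
  fv <- as.numeric(predict(rf, E, num.threads = 1L)$predictions)
  oob_mse <- NA_real_
  if (isTRUE(oob)) {
    oob_pred <- as.numeric(rf$predictions)
    never_oob <- !is.finite(oob_pred)
    if (any(never_oob))
      warning(sprintf(paste0("%d observation(s) never out-of-bag (B too ",
                             "small); excluded from the OOB error."),
                      sum(never_oob)))
    if (!all(never_oob))
      oob_mse <- mean((oob_pred[!never_oob] - H[!never_oob])^2)
  }
  structure(list(family = "forest", fitted = fv, engine = rf,
                 terms = colnames(E),
                 hyperparameters = list(B = B, m = m, max_depth = max_depth,
                                        min_node = min_node, seed = seed,
                                        bootstrap = bootstrap,
                                        sample_fraction = sample_fraction),
                 diagnostics = list(
                   mse = mean((H - fv)^2),
                   r2 = if (var(H) > 0)
                     1 - sum((H - fv)^2) / sum((H - mean(H))^2)
                   else NA_real_,
                   oob_error = oob_mse)),
            class = c("opineq_forest", "opineq_model"))
}

#' @export
predict.opineq_forest <- function(object, newdata, per_tree = FALSE, ...) {
  nd <- as.data.frame(newdata)[, object$terms, drop = FALSE]
  pr <- predict(object$engine, nd, num.threads = 1L,
                predict.all = isTRUE(per_tree))
  if (isTRUE(per_tree)) pr$predictions else as.numeric(pr$predictions)
}

#' Tune tree depth by cross-validated grid search
#'
#' Grid search over tree depths with `folds`-fold cross-validation, scoring
#' by negative mean squared error; ties go to the smallest depth
#' (parsimony).
#'
#' @param family `"cit"` or `"forest"`.
#' @param E,H covariates and outcome.
#' @param grid candidate depths (default 1--20).
#' @param folds number of CV folds.
#' @param seed seed for the fold assignment (and forest randomization).
#' @param ... further arguments to [fit_cit()] / [fit_forest()].
#' @return The selected depth (integer) with the CV curve attached as
#'   attribute `"cv"`.
#' @export
tune_depth <- function(family = c("cit", "forest"), E, H, grid = 1:20,
                       folds = 5, seed = 1, ...) {
  family <- match.arg(family)
  stopifnot(length(grid) >= 1)
  grid <- sort(unique(as.integer(grid)))
  H <- as.numeric(H)
  n <- length(H)
  set.seed(substream(seed, "folds"))
  fold <- sample(rep_len(seq_len(folds), n))
  score <- vapply(grid, function(d) {
    mses <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- if (family == "cit")
        fit_cit(E[tr, , drop = FALSE], H[tr], max_depth = d, ...)
      else
        fit_forest(E[tr, , drop = FALSE], H[tr], max_depth = d, seed = seed,
                   ...)
      mean((predict(fit, E[!tr, , drop = FALSE]) - H[!tr])^2)
    }, numeric(1))
    -mean(mses)
  }, numeric(1))
  best <- grid[which.max(score)]
  structure(best, cv = tibble::tibble(depth = grid, neg_mse = score))
}

#' Test-set fit diagnostics
#'
#' Mean squared error and coefficient of determination of a fitted model on
#' held-out data. A constant test outcome makes R^2 undefined (returned as
#' `NaN` with a warning).
#'
#' @param model a fitted `opineq_model`.
#' @param E_test,H_test held-out covariates and outcome.
#' @return A one-row tibble with `mse` and `r2`.
#' @export
evaluate <- function(model, E_test, H_test) {
  stopifnot(inherits(model, "opineq_model"))
  H_test <- as.numeric(H_test)
  pred <- predict(model, E_test)
  mse <- mean((H_test - pred)^2)
  sst <- sum((H_test - mean(H_test))^2)
  if (sst == 0) {
    warning("Constant test outcome: R^2 undefined.")
    r2 <- NaN
  } else r2 <- 1 - sum((H_test - pred)^2) / sst
  tibble::tibble(mse = mse, r2 = r2)
}

#' @export
print.opineq_model <- function(x, ...) {
  cat(sprintf("<opineq %s model: n = %d, in-sample MSE %.4f, R^2 %.4f>\n",
              x$family, length(x$fitted), x$diagnostics$mse,
              x$diagnostics$r2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.opineq_linear <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @exportS3Method generics::tidy
tidy.opineq_forest <- function(x, ...) {
  imp <- x$engine$variable.importance
  tibble::tibble(variable = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @exportS3Method generics::glance
glance.opineq_model <- function(x, ...) {
  tibble::tibble(family = x$family, n = length(x$fitted),
                 depth = x$hyperparameters$max_depth %||% NA_integer_,
                 mse = x$diagnostics$mse, r2 = x$diagnostics$r2,
                 oob_error = x$diagnostics$oob_error)
}
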