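#' Permutation-based association test between one covariate and the outcome
#'
#' Tests the null of no association (independence) between a candidate split
#' variable and the health outcome with the standardized linear statistic
#' `T = sum(x_i * y_i)`, standardized by its exact permutation mean and
#' variance. The p-value comes either from the asymptotic standard-normal
#' approximation (default) or from Monte-Carlo permutation of the outcome.
#' Constant variables return p = 1 by convention.
#'
#' @param x numeric covariate.
#' @param H numeric outcome.
#' @param method `"asymptotic"` or `"montecarlo"`.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed seed for the Monte-Carlo null (deterministic given seed).
#' @return The two-sided p-value.
#' @export
cit_test <- function(x, H, method = c("asymptotic", "montecarlo"),
                     n_perm = 9999, seed = 1) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(H), length(x) == length(H))
  if (method == "asymptotic") {
    res <- cit_assoc_cpp(matrix(as.numeric(x), ncol = 1), as.numeric(H),
                         seq_along(x) - 1L)
    res$p[1]
  } else {
    cit_perm_pvalue_cpp(as.numeric(x), as.numeric(H), as.integer(n_perm),
                        as.integer(seed))
  }
}

#' Fit a conditional inference tree
#'
#' Recursive partitioning where split variables are chosen by statistical
#' significance rather than impurity: at each node a global independence
#' test is run for every candidate covariate, p-values are Bonferroni
#' adjusted across the candidates, and the node splits on the most
#' significant variable only if its adjusted p-value falls below `alpha`.
#' The split point is found by exhaustive search, maximizing the absolute
#' standardized two-sample statistic between the candidate subsamples (ties
#' broken toward the smallest cutpoint). Nodes stop splitting when the
#' global test is not rejected, the depth limit is reached, or the node is
#' smaller than `min_node`.
#'
#' @param E data frame of environmental covariates (all numeric).
#' @param H numeric health outcome.
#' @param alpha significance level for the (adjusted) global node test.
#' @param max_depth maximum tree depth (`Inf` = grown until tests stop).
#' @param min_node minimum node size to attempt a split.
#' @param min_bucket minimum observations in each child.
#' @param test p-value method, see [cit_test()].
#' @param n_perm,seed Monte-Carlo settings when `test = "montecarlo"`.
#' @return A `opineq_cit` / `opineq_model` object with fitted values, node
#'   table and a prediction method.
#' @export
fit_cit <- function(E, H, alpha = 0.05, max_depth = Inf, min_node = 20,
                    min_bucket = 7, test = c("asymptotic", "montecarlo"),
                    n_perm = 9999, seed = 1) {
  test <- match.arg(test)
  stopifnot(is.data.frame(E) || is.matrix(E), alpha > 0, alpha < 1,
            max_depth >= 0)
  X <- as.matrix(E)
  storage.mode(X) <- "double"
  H <- as.numeric(H)
  stopifnot(nrow(X) == length(H))
  k <- ncol(X)
  st <- new.env(parent = emptyenv())
  st$feature <- integer(0); st$threshold <- numeric(0)
  st$left <- integer(0); st$right <- integer(0)
  st$value <- numeric(0); st$n <- integer(0); st$p_adj <- numeric(0)
  new_node <- function() {
    id <- length(st$feature) + 1L
    st$feature[id] <- -1L; st$threshold[id] <- NA_real_
    st$left[id] <- -1L; st$right[id] <- -1L
    st$value[id] <- NA_real_; st$n[id] <- 0L; st$p_adj[id] <- NA_real_
    id
  }
  grow <- function(rows, depth) {
    id <- new_node()
    st$value[id] <- mean(H[rows])
    st$n[id] <- length(rows)
    if (depth >= max_depth || length(rows) < min_node) return(id)
    if (test == "asymptotic") {
      p <- cit_assoc_cpp(X, H, rows - 1L)$p
    } else {
      p <- vapply(seq_len(k), function(j)
        cit_perm_pvalue_cpp(X[rows, j], H[rows], as.integer(n_perm),
                            as.integer(seed + 7L * j + id)), numeric(1))
    }
    p_adj <- pmin(1, k * p)
    j <- which.min(p_adj)
    st$p_adj[id] <- p_adj[j]
    if (p_adj[j] >= alpha) return(id)
    sp <- cit_split_cpp(X[, j], H, rows - 1L, as.integer(min_bucket))
    if (!isTRUE(sp$ok)) return(id)
    le <- rows[X[rows, j] <= sp$point]
    ri <- rows[X[rows, j] > sp$point]
    st$feature[id] <- j - 1L
    st$threshold[id] <- sp$point
    lid <- grow(le, depth + 1L)
    rid <- grow(ri, depth + 1L)
    st$feature[id] <- j - 1L  # ids allocated depth-first; reassert after
    st$left[id] <- lid - 1L
    st$right[id] <- rid - 1L
    id
  }
  root <- grow(seq_len(nrow(X)), 0L)
  flat <- list(feature = st$feature, threshold = st$threshold,
               left = st$left, right = st$right, value = st$value,
               cover = as.numeric(st$n), tree_start = 0L)
  fitted_vals <- as.numeric(tree_predict_cpp(flat$feature, flat$threshold,
                                             flat$left, flat$right,
                                             flat$value, flat$tree_start, X))
  structure(list(family = "cit", fitted = fitted_vals, flat = flat,
                 terms = colnames(X),
                 nodes = tibble::tibble(
                   id = seq_along(st$feature),
                   variable = ifelse(st$feature >= 0,
                                     colnames(X)[st$feature + 1L], NA),
                   threshold = st$threshold, n = st$n, mean = st$value,
                   p_adjusted = st$p_adj,
                   left = ifelse(st$left >= 0, st$left + 1L, NA),
                   right = ifelse(st$right >= 0, st$right + 1L, NA)),
                 hyperparameters = list(alpha = alpha, max_depth = max_depth,
                                        min_node = min_node,
                                        min_bucket = min_bucket,
                                        test = test, seed = seed),
                 diagnostics = list(
                   mse = mean((H - fitted_vals)^2),
                   r2 = if (var(H) > 0) 1 - sum((H - fitted_vals)^2) /
                     sum((H - mean(H))^2) else NA_real_,
                   oob_error = NA_real_)),
            class = c("opineq_cit", "opineq_model"))
}

#' @export
predict.opineq_cit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$terms, drop = FALSE])
  storage.mode(X) <- "double"
  as.numeric(tree_predict_cpp(object$flat$feature, object$flat$threshold,
                              object$flat$left, object$flat$right,
                              object$flat$value, object$flat$tree_start, X))
}

#' @export
print.opineq_cit <- function(x, ...) {
  n_leaves <- sum(x$flat$feature < 0)
  cat(sprintf("<conditional inference tree: %d nodes (%d leaves), n = %d>\n",
              length(x$flat$feature), n_leaves, x$flat$cover[1]))
  cat(sprintf("  alpha = %g, in-sample R^2 = %.4f\n",
              x$hyperparameters$alpha, x$diagnostics$r2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.opineq_cit <- function(x, ...) x$nodes
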