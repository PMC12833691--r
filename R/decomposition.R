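#' Describe a refittable model for coalition evaluation
#'
#' A recipe records a model family and its hyperparameters so the model can
#' be refit on arbitrary covariate subsets during Shapley decomposition.
#' Forest refits reuse one fixed seed per coalition and default to a reduced
#' number of trees (an approximation knob keeping full coalition enumeration
#' at desk scale).
#'
#' @param family `"linear"`, `"cit"` or `"forest"`.
#' @param ... hyperparameters forwarded to the fitting function. For forests
#'   `B` defaults to 100 here.
#' @return A `opineq_recipe` object.
#' @export
model_recipe <- function(family = c("linear", "cit", "forest"), ...) {
  family <- match.arg(family)
  args <- list(...)
  if (family == "forest") {
    if (is.null(args$B)) args$B <- 100
    if (is.null(args$oob)) args$oob <- FALSE
  }
  structure(list(family = family, args = args), class = "opineq_recipe")
}

# Returns fit(cols) -> in-sample fitted values of the model refit on the
# covariate subset `cols`. Linear refits solve from a cached Gram matrix
# (with a pivoted-QR fallback for singular subsets, e.g. duplicated
# columns).
prepare_recipe <- function(recipe, E, H) {
  stopifnot(inherits(recipe, "opineq_recipe"))
  E <- as.data.frame(E)
  H <- as.numeric(H)
  if (recipe$family == "linear") {
    X1 <- cbind(`(Intercept)` = 1, as.matrix(E))
    G <- crossprod(X1)
    Gy <- crossprod(X1, H)
    function(cols) {
      idx <- c(1L, cols + 1L)
      b <- tryCatch(solve(G[idx, idx, drop = FALSE], Gy[idx, ]),
                    error = function(e) {
                      qr_b <- qr.coef(qr(X1[, idx, drop = FALSE]), H)
                      qr_b[is.na(qr_b)] <- 0
                      qr_b
                    })
      as.numeric(X1[, idx, drop = FALSE] %*% b)
    }
  } else if (recipe$family == "cit") {
    function(cols) {
      do.call(fit_cit, c(list(E = E[, cols, drop = FALSE], H = H),
                         recipe$args))$fitted
    }
  } else {
    function(cols) {
      args <- recipe$args
      if (!is.null(args$m)) args$m <- min(args$m, length(cols))
      do.call(fit_forest, c(list(E = E[, cols, drop = FALSE], H = H),
                            args))$fitted
    }
  }
}

#' Coalition value: inequality of the subset-refit smoothed distribution
#'
#' `v(S)` is the MLD of the fitted values of the model refit using only the
#' covariates in `S`; the empty coalition predicts the grand mean for
#' everyone, so `v(empty) = 0`.
#'
#' @param S integer vector of covariate column indices (possibly empty).
#' @param E,H covariates and health outcome.
#' @param recipe a [model_recipe()].
#' @return The coalition value (nonnegative number).
#' @export
coalition_value <- function(S, E, H, recipe) {
  if (length(S) == 0L) return(0)
  fitter <- prepare_recipe(recipe, E, H)
  mld(fitter(sort(unique(as.integer(S)))))
}

#' Exact Shapley decomposition of absolute opportunity inequality
#'
#' Attributes `theta_a` to individual covariates by the Shapley value over
#' all `2^k` covariate coalitions, refitting the model on each subset.
#' Satisfies efficiency (contributions sum to `theta_a`), symmetry and the
#' dummy axiom by construction. Small negative contributions are possible
#' because the MLD is not additively separable; they are reported as-is.
#'
#' @param E,H covariates and health outcome.
#' @param recipe a [model_recipe()].
#' @param exact_limit refuse enumeration beyond this many covariates.
#' @return A `opineq_contrib` tibble (`variable`, `phi`, `share` in percent)
#'   with `theta_a`, `method = "exact"` and the coalition evaluation count
#'   as attributes.
#' @export
shapley_exact <- function(E, H, recipe, exact_limit = 13) {
  E <- as.data.frame(E)
  k <- ncol(E)
  if (k > exact_limit)
    stop(sprintf(paste0("k = %d exceeds the exact enumeration limit (%d); ",
                        "use shapley_sampled() or the tree-attribution ",
                        "surrogate."), k, exact_limit), call. = FALSE)
  fitter <- prepare_recipe(recipe, E, H)
  n_masks <- 2L^k
  v <- numeric(n_masks)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (mask in seq_len(n_masks - 1L)) {
    cols <- which(bitwAnd(mask, bits) > 0L)
    v[mask + 1L] <- mld(fitter(cols))
  }
  phi <- shapley_from_values(v, k)
  new_contrib_table(colnames(E), phi, theta_a = v[n_masks],
                    method = "exact", family = recipe$family,
                    n_evals = n_masks)
}

#' Monte-Carlo (permutation-sampling) Shapley decomposition
#'
#' Unbiased sampling estimate of the exact decomposition: covariate
#' orderings are drawn at random and each variable is credited its marginal
#' contribution when appended to its predecessors. Coalition values are
#' cached across permutations. When `n_perm` reaches `k!` (and `k <= 6`) all
#' distinct orderings are enumerated exactly once, reproducing
#' [shapley_exact()].
#'
#' @param E,H covariates and health outcome.
#' @param recipe a [model_recipe()].
#' @param n_perm number of sampled permutations.
#' @param seed sampling seed.
#' @return A `opineq_contrib` tibble with a per-variable standard error
#'   column `se`.
#' @export
shapley_sampled <- function(E, H, recipe, n_perm = 200, seed = 1) {
  stopifnot(n_perm >= 1)
  E <- as.data.frame(E)
  k <- ncol(E)
  fitter <- prepare_recipe(recipe, E, H)
  cache <- new.env(parent = emptyenv())
  value_of <- function(mask, cols) {
    key <- as.character(mask)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (length(cols) == 0L) 0 else mld(fitter(cols))
    cache[[key]] <- val
    val
  }
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(all_perms(v[-i]), function(p) c(v[i], p))))
  }
  exhaustive <- k <= 6 && n_perm >= factorial(k)
  perms <- if (exhaustive) all_perms(seq_len(k)) else {
    set.seed(substream(seed, "shapley"))
    lapply(seq_len(n_perm), function(i) sample.int(k))
  }
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  marg <- matrix(NA_real_, length(perms), k)
  for (p in seq_along(perms)) {
    mask <- 0L
    cols <- integer(0)
    v_prev <- 0
    for (j in perms[[p]]) {
      cols <- c(cols, j)
      mask <- mask + bits[j]
      v_new <- value_of(mask, cols)
      marg[p, j] <- v_new - v_prev
      v_prev <- v_new
    }
  }
  phi <- colMeans(marg)
  se <- if (exhaustive) rep(0, k) else
    apply(marg, 2, sd) / sqrt(length(perms))
  theta_a <- value_of(sum(bits), seq_len(k))
  out <- new_contrib_table(colnames(E), phi, theta_a = theta_a,
                           method = if (exhaustive) "exact" else "sampled",
                           family = recipe$family,
                           n_evals = length(ls(cache)), se = se)
  out
}

# Flatten a fitted tree model into the arrays the C++ SHAP kernel expects,
# with covers recomputed from a background dataset.
flatten_trees <- function(model, X) {
  if (inherits(model, "opineq_cit")) {
    fl <- model$flat
    trees <- list(feature = fl$feature, threshold = fl$threshold,
                  left = fl$left, right = fl$right, value = fl$value,
                  tree_start = 0L)
  } else if (inherits(model, "opineq_forest")) {
    rf <- model$engine
    B <- rf$num.trees
    parts <- lapply(seq_len(B), function(b) {
      ti <- ranger::treeInfo(rf, b)
      list(feature = ifelse(ti$terminal, -1L, as.integer(ti$splitvarID)),
           threshold = ifelse(ti$terminal, 0, as.numeric(ti$splitval)),
           left = ifelse(ti$terminal, -1L, as.integer(ti$leftChild)),
           right = ifelse(ti$terminal, -1L, as.integer(ti$rightChild)),
           value = ifelse(ti$terminal, as.numeric(ti$prediction), 0))
    })
    sizes <- vapply(parts, function(p) length(p$feature), integer(1))
    trees <- list(feature = unlist(lapply(parts, `[[`, "feature")),
                  threshold = unlist(lapply(parts, `[[`, "threshold")),
                  left = unlist(lapply(parts, `[[`, "left")),
                  right = unlist(lapply(parts, `[[`, "right")),
                  value = unlist(lapply(parts, `[[`, "value")),
                  tree_start = as.integer(cumsum(c(0L, sizes[-B]))))
    # child ids in treeInfo are tree-local; offset into the flat arrays
    off <- rep(trees$tree_start, sizes)
    trees$left <- ifelse(trees$left >= 0L, trees$left + off, -1L)
    trees$right <- ifelse(trees$right >= 0L, trees$right + off, -1L)
  } else {
    stop("Per-observation attribution requires a tree-based model.",
         call. = FALSE)
  }
  trees$cover <- as.numeric(tree_cover_cpp(trees$feature, trees$threshold,
                                           trees$left, trees$right,
                                           trees$tree_start, X))
  trees
}

#' Per-observation additive feature attributions for tree models
#'
#' Path-dependent SHAP attributions computed by the polynomial-time
#' tree-traversal algorithm (complexity `O(T L D^2)` instead of `O(2^k)`).
#' Marginal contributions follow the tree's own cover proportions, which
#' implicitly assumes feature independence. Local accuracy holds on every
#' row: base value + row sum = the model's prediction.
#'
#' @param model a fitted `opineq_cit` or `opineq_forest`.
#' @param E rows to attribute (typically the analysis sample or a subsample
#'   of it).
#' @param background data whose paths define the node covers (defaults to
#'   `E`; pass the full training sample when `E` is a subsample, so every
#'   tree node keeps positive cover).
#' @return An `n x k` matrix of class `opineq_attribution` with attribute
#'   `base` (the ensemble mean prediction over the background).
#' @export
attribution_matrix <- function(model, E, background = E) {
  stopifnot(inherits(model, "opineq_model"))
  X <- as.matrix(as.data.frame(E)[, model$terms, drop = FALSE])
  storage.mode(X) <- "double"
  Xb <- as.matrix(as.data.frame(background)[, model$terms, drop = FALSE])
  storage.mode(Xb) <- "double"
  trees <- flatten_trees(model, Xb)
  res <- treeshap_cpp(trees$feature, trees$threshold, trees$left,
                      trees$right, trees$value, trees$cover,
                      trees$tree_start, X)
  phi <- res$phi
  colnames(phi) <- model$terms
  structure(phi, base = res$base, family = model$family,
            class = c("opineq_attribution", class(phi)))
}

#' Inequality contribution shares from additive tree attributions
#'
#' The fast surrogate for the exact (retraining) decomposition: using the
#' local-accuracy identity `prediction_i = base + sum_j phi_ij`, coalition
#' predictions are defined additively as `h_i(S) = base + sum_{j in S}
#' phi_ij`, the coalition value is the MLD of those surrogate predictions,
#' and the Shapley value is taken over this cheap value function by exact
#' enumeration (no retraining). If any surrogate prediction is nonpositive
#' the common shift is escalated with a warning.
#'
#' @param attrib an [attribution_matrix()].
#' @param shift extra shift added to all surrogate predictions (default 0:
#'   attributions from a model fit on the shifted scale already have a
#'   positive base).
#' @return A `opineq_contrib` tibble, `method = "surrogate"`.
#' @export
surrogate_inequality_shares <- function(attrib, shift = 0) {
  stopifnot(inherits(attrib, "opineq_attribution"))
  A <- unclass(attrib)
  base <- attr(attrib, "base")
  k <- ncol(A)
  n <- nrow(A)
  worst <- base + shift + rowSums(pmin(A, 0))
  if (min(worst) <= 0) {
    delta <- 1e-6 - min(worst)
    warning(sprintf(paste0("Nonpositive surrogate predictions; escalating ",
                           "shift by %.4g."), delta))
    shift <- shift + delta
  }
  order_gray <- gray_code_order(k)
  v <- numeric(2L^k)
  h <- rep(base + shift, n)
  prev <- 0L
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (i in seq_along(order_gray)) {
    mask <- order_gray[i]
    changed <- bitwXor(mask, prev)
    if (changed != 0L) {
      j <- which(bits == changed)
      if (bitwAnd(mask, changed) > 0L) h <- h + A[, j] else h <- h - A[, j]
    }
    v[mask + 1L] <- if (mask == 0L) 0 else mld(h)
    prev <- mask
  }
  phi <- shapley_from_values(v, k)
  new_contrib_table(colnames(A), phi, theta_a = v[2L^k],
                    method = "surrogate", family = attr(attrib, "family"),
                    n_evals = 2L^k)
}
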