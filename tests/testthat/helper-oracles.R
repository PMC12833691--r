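# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# loop-based mean log deviation
mld_brute <- function(y) {
  mu <- sum(y) / length(y)
  s <- 0
  for (yi in y) s <- s + log(mu / yi)
  s / length(y)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# permutation-form Shapley over coalition values computed by retraining:
# phi_j = average over orderings of the marginal contribution of j
shapley_perm_brute <- function(E, H, recipe) {
  k <- ncol(E)
  vcache <- new.env(parent = emptyenv())
  vfun <- function(S) {
    key <- paste(sort(S), collapse = ",")
    if (is.null(vcache[[key]]))
      vcache[[key]] <- coalition_value(S, E, H, recipe)
    vcache[[key]]
  }
  phi <- numeric(k)
  perms <- all_permutations(k)
  for (p in perms) {
    S <- integer(0)
    v_prev <- 0
    for (j in p) {
      S <- c(S, j)
      v_new <- vfun(S)
      phi[j] <- phi[j] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / length(perms)
}

# cover-weighted conditional expectation of a flat tree given feature set S
tree_expval_brute <- function(flat, x, S, node = 1L) {
  f <- flat$feature[node] + 1L
  if (f == 0L) return(flat$value[node])
  l <- flat$left[node] + 1L
  r <- flat$right[node] + 1L
  if (f %in% S) {
    if (x[f] <= flat$threshold[node]) tree_expval_brute(flat, x, S, l)
    else tree_expval_brute(flat, x, S, r)
  } else {
    (flat$cover[l] * tree_expval_brute(flat, x, S, l) +
       flat$cover[r] * tree_expval_brute(flat, x, S, r)) / flat$cover[node]
  }
}

# per-observation Shapley attributions of a flat tree by subset enumeration
tree_shap_brute <- function(flat, x, k) {
  phi <- numeric(k)
  for (j in seq_len(k)) {
    for (mask in 0:(2^k - 1L)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0L) next
      S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L)
      s <- length(S)
      w <- factorial(s) * factorial(k - s - 1) / factorial(k)
      phi[j] <- phi[j] + w * (tree_expval_brute(flat, x, c(S, j)) -
                                tree_expval_brute(flat, x, S))
    }
  }
  phi
}

# plain-R re-implementation of the node-level CIT selection and split rule,
# for agreement checks on tiny instances
cit_root_oracle <- function(E, H, min_bucket = 7) {
  X <- as.matrix(E)
  n <- nrow(X)
  k <- ncol(X)
  pvals <- vapply(seq_len(k), function(j) {
    x <- X[, j]
    vx <- sum((x - mean(x))^2)
    vy <- sum((H - mean(H))^2)
    if (vx <= 1e-12 || vy <= 1e-12) return(1)
    t_stat <- sum(x * H)
    mu <- sum(x) * sum(H) / n
    sig <- sqrt(vx * vy / (n - 1))
    2 * pnorm(-abs((t_stat - mu) / sig))
  }, numeric(1))
  p_adj <- pmin(1, k * pvals)
  j <- which.min(p_adj)
  x <- X[, j]
  ord <- order(x)
  best <- -Inf
  best_c <- NA_real_
  ybar <- mean(H)
  ssy <- sum((H - ybar)^2)
  for (i in seq_len(n - 1)) {
    nl <- i
    if (nl < min_bucket || (n - nl) < min_bucket) next
    if (x[ord[i]] >= x[ord[i + 1]]) next
    sl <- sum(H[ord[seq_len(i)]])
    z <- abs(sl - nl * ybar) / sqrt(nl * (n - nl) / (n * (n - 1)) * ssy)
    if (z > best + 1e-12) {
      best <- z
      best_c <- (x[ord[i]] + x[ord[i + 1]]) / 2
    }
  }
  list(variable = j, p_adj = p_adj[j], point = best_c, stat = best)
}

# hand-built flat tree constructor (0-based children, -1 = leaf)
make_flat_tree <- function(feature, threshold, left, right, value, cover) {
  list(feature = as.integer(feature), threshold = as.numeric(threshold),
       left = as.integer(left), right = as.integer(right),
       value = as.numeric(value), cover = as.numeric(cover),
       tree_start = 0L)
}

# small patient-record table for preprocessing tests
toy_records <- function(sizes = c(10, 30, 31, 100, 2), seed = 1) {
  set.seed(seed)
  groups <- sprintf("I%02d0", seq_along(sizes) + 10)
  tibble::tibble(
    age = 50 + sample(0:30, sum(sizes), replace = TRUE),
    icd10_group = rep(groups, sizes),
    total_expenses = rlnorm(sum(sizes), 8, 0.5),
    primary_dx = sample(1:4, sum(sizes), replace = TRUE,
                        prob = c(.4, .4, .15, .05)),
    secondary_dx = ""
  )
}
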