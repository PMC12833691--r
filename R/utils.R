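# Internal helpers shared across modules.

# Derive a reproducible child seed from a root seed and a stage label, kept
# within 32-bit integer range.
substream <- function(seed, stage) {
  offsets <- c(generate = 11, models = 23, folds = 37, shapley = 53,
               quantile = 71, pipeline = 97, oracle = 131)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 151
  as.integer((as.double(seed) * 1103L + off * 100003) %% 2147483647)
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1].", name),
         call. = FALSE)
  invisible(x)
}

# Moments of a normal truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  m <- mu + sigma * (dnorm(al) - dnorm(be)) / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z -
                    ((dnorm(al) - dnorm(be)) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for parent (mu, sigma) so that the [a, b]-truncated normal has the
# requested mean and sd. Needed because truncation shrinks the variance:
# plugging the target moments in directly would generate too-narrow data.
truncnorm_solve <- function(mean, sd, a, b) {
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mom["mean"] - mean)^2 / sd^2 + (mom["sd"] - sd)^2 / sd^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), a = a, b = b,
       converged = fit$convergence == 0)
}

rtruncnorm <- function(n, mu, sigma, a, b) {
  lo <- pnorm((a - mu) / sigma)
  hi <- pnorm((b - mu) / sigma)
  qnorm(runif(n, lo, hi)) * sigma + mu
}

qtruncnorm <- function(p, mu, sigma, a, b) {
  lo <- pnorm((a - mu) / sigma)
  hi <- pnorm((b - mu) / sigma)
  qnorm(lo + p * (hi - lo)) * sigma + mu
}

# Probabilities of a 3-level categorical on `levels` matching mean and sd
# exactly (two moment equations + normalization).
cat3_probs <- function(levels, mean, sd) {
  stopifnot(length(levels) == 3)
  x <- levels - levels[1]
  m <- mean - levels[1]
  m2 <- sd^2 + m^2
  # p1*x2 + p2*x3 = m ; p1*x2^2 + p2*x3^2 = m2
  A <- rbind(c(x[2], x[3]), c(x[2]^2, x[3]^2))
  p <- solve(A, c(m, m2))
  probs <- c(1 - sum(p), p)
  if (any(probs < -1e-9))
    stop("No valid 3-level categorical matches these moments.", call. = FALSE)
  pmax(probs, 0) / sum(pmax(probs, 0))
}

# 4-level categorical with the top-level probability fixed (one spare
# degree of freedom); used for admission condition where level-4 cases are
# rare.
cat4_probs <- function(levels, mean, sd, p_top) {
  stopifnot(length(levels) == 4)
  x <- levels - levels[1]
  m <- mean - levels[1] - p_top * x[4]
  m2 <- sd^2 + (mean - levels[1])^2 - p_top * x[4]^2
  A <- rbind(c(x[2], x[3]), c(x[2]^2, x[3]^2))
  p <- solve(A, c(m, m2))
  probs <- c(1 - sum(p) - p_top, p, p_top)
  if (any(probs < -1e-9))
    stop("No valid 4-level categorical matches these moments.", call. = FALSE)
  pmax(probs, 0) / sum(pmax(probs, 0))
}

# Shapley values from a coalition value vector v indexed by bitmask + 1
# (v[1] = v(empty set)). Returns phi of length k with sum(phi) =
# v(full) - v(empty) by construction.
shapley_from_values <- function(v, k) {
  n_masks <- 2^k
  stopifnot(length(v) == n_masks)
  pop <- integer(n_masks)
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    pop <- pop + (bitwAnd(seq_len(n_masks) - 1L, bit) > 0L)
  }
  # weight by coalition size s = |S| (S excludes j): s! (k-s-1)! / k!
  wt <- exp(lgamma(0:(k - 1) + 1) + lgamma(k - (0:(k - 1))) - lgamma(k + 1))
  phi <- numeric(k)
  masks <- seq_len(n_masks) - 1L
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    phi[j] <- sum(wt[pop[without + 1L] + 1L] *
                    (v[without + bit + 1L] - v[without + 1L]))
  }
  phi
}

gray_code_order <- function(k) {
  i <- 0:(2^k - 1)
  bitwXor(i, i %/% 2L)
}

new_contrib_table <- function(variable, phi, theta_a, method, family,
                              n_evals, se = NULL) {
  share <- if (abs(theta_a) > 0) phi / theta_a * 100 else rep(NA_real_, length(phi))
  out <- tibble::tibble(variable = variable, phi = phi, share = share)
  if (!is.null(se)) out$se <- se
  structure(out, theta_a = theta_a, method = method, family = family,
            n_evals = n_evals,
            class = c("opineq_contrib", class(out)))
}

#' @export
print.opineq_contrib <- function(x, ...) {
  cat(sprintf("<opineq contribution table: %s Shapley, %s model>\n",
              attr(x, "method"), attr(x, "family")))
  cat(sprintf("  theta_a = %.6g over %d coalition evaluations\n",
              attr(x, "theta_a"), attr(x, "n_evals")))
  NextMethod()
}
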