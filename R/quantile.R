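#' Recentered influence function of an unconditional quantile
#'
#' `RIF_i = q_tau + (tau - 1{H_i <= q_tau}) / f(q_tau)` with the
#' linear-interpolation sample quantile and a Gaussian-kernel density
#' estimate at the quantile (Silverman's rule-of-thumb bandwidth). The RIF
#' takes exactly two values and its sample mean is close to the quantile
#' (within `1/(n f)` of it).
#'
#' @param H numeric outcome (at least 30 observations).
#' @param tau quantile level in (0, 1).
#' @param bandwidth kernel bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]).
#' @return Numeric vector with attributes `q` (the quantile), `f` (density
#'   at the quantile) and `bandwidth`.
#' @export
rif <- function(H, tau, bandwidth = NULL) {
  H <- as.numeric(H)
  stopifnot(length(H) >= 30, tau > 0, tau < 1)
  if (sd(H) == 0) stop("Degenerate outcome: RIF undefined.", call. = FALSE)
  q <- quantile(H, tau, type = 7, names = FALSE)
  below <- H <= q
  if (all(below) || !any(below))
    stop(paste0("Degenerate RIF: the quantile falls on the boundary of a ",
                "discrete outcome (the indicator is constant); choose ",
                "another tau or a finer-grained outcome."), call. = FALSE)
  h <- bandwidth %||% bw.nrd0(H)
  f <- mean(dnorm((H - q) / h)) / h
  if (!is.finite(f) || f <= 0)
    stop("Density estimate at the quantile is not positive.", call. = FALSE)
  structure(q + (tau - below) / f, q = q, f = f, bandwidth = h)
}

#' Unconditional quantile regression (RIF regression)
#'
#' OLS of the recentered influence function of the `tau`-quantile on the
#' environmental covariates with an intercept (no fixed effects). The
#' coefficients estimate the effect of each covariate on the unconditional
#' `tau`-quantile of the outcome distribution.
#'
#' @param E data frame of covariates.
#' @param H numeric outcome.
#' @param tau quantile level.
#' @return A `opineq_uqr` object: coefficient tibble, fitted RIF values,
#'   the RIF vector, and `q`, `f`, `bandwidth`.
#' @export
uqr_fit <- function(E, H, tau) {
  r <- rif(H, tau)
  fit <- fit_linear(E, as.numeric(r))
  structure(list(tau = tau, coefficients = tidy(fit), fitted = fit$fitted,
                 rif = as.numeric(r), q = attr(r, "q"), f = attr(r, "f"),
                 bandwidth = attr(r, "bandwidth"), model = fit),
            class = "opineq_uqr")
}

#' Per-quantile opportunity inequality with Shapley decomposition
#'
#' For each quantile level, the RIF of the outcome is regressed on the
#' environment; a single positivity shift (shared across all quantiles so
#' cross-quantile comparisons stay on one scale) is chosen so every actual
#' and fitted RIF value is at least `eps`; `theta_a(tau)` is the MLD of the
#' shifted fitted RIF, `theta_r(tau)` its ratio to the MLD of the shifted
#' actual RIF; and the contribution of each covariate is the exact Shapley
#' value over OLS refits of the RIF regression on covariate subsets.
#'
#' @param E data frame of environmental covariates.
#' @param H numeric health outcome.
#' @param taus quantile levels (default 0.25, 0.50, 0.75).
#' @param eps minimum value of the shifted RIF scale.
#' @param decompose run the per-quantile Shapley decomposition.
#' @param on_degenerate `"error"` (default) to propagate degenerate-RIF
#'   errors (a quantile sitting on the boundary atom of a discrete
#'   outcome), or `"na"` to report `NA` for the affected quantiles with a
#'   warning and keep the rest.
#' @return A `opineq_quantile` object: `summary` tibble (one row per tau:
#'   `tau`, `q`, `f`, `bandwidth`, `theta_a`, `theta_r`), `contributions`
#'   tibble (tau x variable shares), `coefficients` tibble, and the common
#'   `shift`.
#' @export
quantile_iop <- function(E, H, taus = c(0.25, 0.5, 0.75), eps = 1,
                         decompose = TRUE,
                         on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  E <- as.data.frame(E)
  H <- as.numeric(H)
  fits <- lapply(taus, function(tau) {
    if (on_degenerate == "error") return(uqr_fit(E, H, tau))
    tryCatch(uqr_fit(E, H, tau), error = function(e) {
      warning(sprintf("tau = %.2f: %s", tau, conditionMessage(e)))
      NULL
    })
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("No quantile produced a usable RIF.", call. = FALSE)
  lo <- min(vapply(fits[ok], function(f) min(f$rif, f$fitted), numeric(1)))
  shift <- max(0, eps - lo)
  summaries <- purrr::map2_dfr(fits, taus, function(ft, tau) {
    if (is.null(ft))
      return(tibble::tibble(tau = tau, q = NA_real_, f = NA_real_,
                            bandwidth = NA_real_, theta_a = NA_real_,
                            theta_r = NA_real_))
    theta_a <- mld(ft$fitted + shift)
    tibble::tibble(tau = tau, q = ft$q, f = ft$f, bandwidth = ft$bandwidth,
                   theta_a = theta_a,
                   theta_r = theta_a / mld(ft$rif + shift))
  })
  contribs <- NULL
  if (decompose) {
    contribs <- purrr::map2_dfr(fits[ok], taus[ok], function(ft, tau) {
      ct <- shapley_exact(E, ft$rif + shift, model_recipe("linear"))
      dplyr::mutate(tibble::as_tibble(ct), tau = tau, .before = 1)
    })
  }
  coefs <- purrr::map2_dfr(fits[ok], taus[ok], function(ft, tau)
    dplyr::mutate(ft$coefficients, tau = tau, .before = 1))
  structure(list(summary = summaries, contributions = contribs,
                 coefficients = coefs, shift = shift),
            class = "opineq_quantile")
}

#' @export
print.opineq_quantile <- function(x, ...) {
  cat("<opineq per-quantile opportunity inequality>\n")
  print(x$summary)
  invisible(x)
}
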