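#' Mean log deviation
#'
#' `MLD(y) = mean(log(mean(y) / y))`: zero iff all values are equal,
#' invariant to rescaling, *not* invariant to translation (which is why the
#' positivity shift applied upstream is carried as declared metadata).
#'
#' @param values strictly positive numeric vector.
#' @return A nonnegative number.
#' @examples
#' mld(c(1, exp(1)))  # log((1 + e) / 2) - 1 / 2
#' @export
mld <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("`values` must be non-missing.", call. = FALSE)
  if (any(values <= 0))
    stop("MLD requires strictly positive values; apply a positivity shift.",
         call. = FALSE)
  mean(log(mean(values) / values))
}

#' Absolute and relative opportunity inequality of a fitted model
#'
#' Ex-ante parametric IOp: the absolute index `theta_a` is the MLD of the
#' model's fitted (counterfactual, environment-smoothed) health values; the
#' relative index `theta_r` divides it by the MLD of the actual health
#' distribution. `theta_r` above 1 is possible for overfit smoothers in
#' finite samples and triggers a warning -- it is reported as-is, never
#' clipped.
#'
#' @param model a fitted `opineq_model` (fitted values are the in-sample
#'   predictions on the full analysis sample), or any object with a numeric
#'   `fitted` element.
#' @param H the health vector the model was fitted on (same positive shifted
#'   scale as the fitted values).
#' @param fitted optional explicit fitted values overriding `model$fitted`
#'   (e.g. out-of-sample smoothing).
#' @return A one-row `opineq_iop` tibble: `family`, `variant`, `total_mld`,
#'   `absolute_iop` (theta_a), `relative_iop` (theta_r), `shift`.
#' @export
opportunity_inequality <- function(model, H, fitted = NULL) {
  fv <- fitted %||% model$fitted
  stopifnot(is.numeric(fv), length(fv) == length(H))
  total <- mld(as.numeric(H))
  if (total == 0)
    stop("Total MLD is zero: relative opportunity inequality undefined.",
         call. = FALSE)
  theta_a <- mld(fv)
  theta_r <- theta_a / total
  if (theta_r > 1 || theta_r < 0)
    warning(sprintf("relative IOp %.4f outside [0, 1] (overfit smoother?)",
                    theta_r))
  out <- tibble::tibble(
    family = model$family %||% NA_character_,
    variant = attr(H, "variant") %||% NA_character_,
    total_mld = total, absolute_iop = theta_a, relative_iop = theta_r,
    shift = attr(H, "shift") %||% NA_real_)
  structure(out, class = c("opineq_iop", class(out)))
}

#' @exportS3Method generics::tidy
tidy.opineq_iop <- function(x, ...) tibble::as_tibble(x)
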