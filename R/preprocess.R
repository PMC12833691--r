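#' Apply the study-population filters
#'
#' Keeps patients aged `min_age` or older, optionally restricts to a set of
#' ICD-10 diagnosis groups, and then drops diagnosis groups with `min_cases`
#' or fewer admissions (strictly more than `min_cases` are required, so a
#' group with exactly 30 cases is dropped under the default).
#'
#' @param records patient-record tibble with `age` and `icd10_group`.
#' @param min_age minimum age retained (default 45).
#' @param icd_codes optional character vector of ICD-10 groups to keep.
#' @param min_cases groups must have strictly more cases than this.
#' @return The filtered tibble.
#' @export
filter_study_population <- function(records, min_age = 45, icd_codes = NULL,
                                    min_cases = 30) {
  stopifnot(is.data.frame(records),
            all(c("age", "icd10_group") %in% names(records)))
  out <- dplyr::filter(records, .data$age >= min_age)
  if (!is.null(icd_codes))
    out <- dplyr::filter(out, .data$icd10_group %in% icd_codes)
  out <- out |>
    dplyr::add_count(.data$icd10_group, name = ".n_group") |>
    dplyr::filter(.data$.n_group > min_cases) |>
    dplyr::select(-".n_group")
  if (nrow(out) == 0L)
    stop("Study filters removed every record (empty population).",
         call. = FALSE)
  out
}

#' Mean-impute missing values
#'
#' Replaces missing entries of every numeric column by the column mean.
#' Columns declared as leveled -- ordinal codes -- and binary (0/1) columns
#' get the mean rounded to the nearest observed level, so level codings stay
#' valid; ties round down. All other columns get the raw arithmetic mean.
#'
#' @param data a data frame.
#' @param leveled character vector of additional column names to treat as
#'   leveled; 0/1 columns are always detected automatically.
#' @return The data frame with no missing numeric entries.
#' @export
impute_means <- function(data, leveled = NULL) {
  stopifnot(is.data.frame(data))
  for (nm in names(data)) {
    x <- data[[nm]]
    if (!is.numeric(x) || !anyNA(x)) next
    ok <- !is.na(x)
    if (!any(ok))
      stop(sprintf("Column `%s` is fully missing; cannot impute.", nm),
           call. = FALSE)
    m <- mean(x[ok])
    lev <- nm %in% leveled || all(x[ok] %in% c(0, 1))
    if (lev) {
      vals <- sort(unique(x[ok]))
      m <- vals[which.min(abs(vals - m))]
    }
    x[!ok] <- m
    data[[nm]] <- x
  }
  data
}

#' Two-sided winsorization
#'
#' Caps values below the `lower_pct` percentile and above the `upper_pct`
#' percentile at those percentiles (linear-interpolation quantiles,
#' `type = 7`). The defaults implement a 1% winsorization.
#'
#' @param values numeric vector.
#' @param lower_pct,upper_pct percentile bounds in `[0, 100]`.
#' @param bounds optional explicit cap values `c(lo, hi)` overriding the
#'   percentiles (capping at fixed values is idempotent; re-estimating
#'   percentiles on already-capped data generally is not).
#' @return The winsorized vector, with the caps as attribute `bounds`.
#' @export
winsorize <- function(values, lower_pct = 1, upper_pct = 99, bounds = NULL) {
  stopifnot(is.numeric(values), lower_pct >= 0, upper_pct <= 100,
            lower_pct <= upper_pct)
  qs <- bounds %||% quantile(values, c(lower_pct, upper_pct) / 100,
                             na.rm = TRUE, names = FALSE, type = 7)
  stopifnot(length(qs) == 2, qs[1] <= qs[2])
  out <- pmin(pmax(values, qs[1]), qs[2])
  attr(out, "bounds") <- as.numeric(qs)
  out
}

#' Fit a rank-based inverse normal transformation for an ordinal variable
#'
#' Maps each ordinal category to the standard-normal quantile of the midpoint
#' of its cumulative-frequency interval: `z_k = qnorm(F_{k-1} + f_k / 2)`.
#' The midpoint convention handles the heavy ties of a four-category outcome,
#' where per-rank (Blom-type) offsets are ill-defined.
#'
#' @param x ordinal vector (integer codes or factor), or a `table` of counts.
#' @param levels the full ordered level set; defaults to the sorted observed
#'   values.
#' @return A `opineq_rint` tibble with columns `level`, `count`, `freq`, `z`.
#' @examples
#' rint_fit(rep(1:4, c(50, 30, 15, 5)))
#' @export
rint_fit <- function(x, levels = NULL) {
  if (inherits(x, "table")) {
    counts <- as.numeric(x)
    lev <- as.numeric(names(x))
  } else {
    if (is.factor(x)) x <- as.integer(as.character(x))
    lev <- levels %||% sort(unique(x[!is.na(x)]))
    counts <- vapply(lev, function(l) sum(x == l, na.rm = TRUE), numeric(1))
  }
  if (sum(counts) == 0)
    stop("No observations to fit the transformation.", call. = FALSE)
  f <- counts / sum(counts)
  z <- qnorm(cumsum(f) - f / 2)
  z[f == 0] <- NA_real_
  if (sum(counts > 0) == 1L) {
    warning("Single observed category: degenerate transformation (z = 0).")
    z[counts > 0] <- 0
  }
  out <- tibble::tibble(level = lev, count = counts, freq = f, z = z)
  structure(out, n = sum(counts),
            class = c("opineq_rint", class(out)))
}

#' Apply a fitted RINT map
#'
#' @param map a [rint_fit()] result.
#' @param x ordinal values to transform.
#' @return Numeric z-scores.
#' @export
rint_apply <- function(map, x) {
  stopifnot(inherits(map, "opineq_rint"))
  map$z[match(x, map$level)]
}

#' Build a continuous health vector from ordinal discharge diagnoses
#'
#' Transforms the ordinal discharge diagnosis through the fitted RINT map,
#' reverses the sign so that higher values mean better health, and adds a
#' positivity shift (the MLD requires strictly positive values; it is
#' scale-invariant but *not* translation-invariant, so the shift is carried
#' as declared metadata on the result). The `composite` variant averages the
#' reversed transformed scores of the primary and all secondary diagnoses.
#'
#' @param records patient records with `primary_dx` (and `secondary_dx` as a
#'   semicolon-separated string for the composite variant).
#' @param variant `"primary"` or `"composite"`.
#' @param rint_map a [rint_fit()] result for the diagnosis categories.
#' @param shift positivity shift (default 5).
#' @return A numeric vector of class `opineq_health` with attributes
#'   `variant` and `shift`.
#' @export
make_health <- function(records, variant = c("primary", "composite"),
                        rint_map, shift = 5) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(records), "primary_dx" %in% names(records),
            shift > 0)
  zmax <- max(rint_map$z, na.rm = TRUE)
  if (shift - zmax <= 0)
    stop(sprintf(paste0("`shift` = %g cannot guarantee positivity; ",
                        "use shift > %g."), shift, zmax), call. = FALSE)
  rev_primary <- -rint_apply(rint_map, records$primary_dx)
  if (variant == "primary") {
    h <- rev_primary + shift
  } else {
    sec <- strsplit(records$secondary_dx %||% rep("", nrow(records)), ";",
                    fixed = TRUE)
    h <- vapply(seq_len(nrow(records)), function(i) {
      s <- sec[[i]]
      s <- s[nzchar(s)]
      if (length(s) == 0L) return(rev_primary[i])
      mean(c(rev_primary[i], -rint_apply(rint_map, as.integer(s))))
    }, numeric(1)) + shift
  }
  if (any(h <= 0))
    stop("Health values not strictly positive; increase `shift`.",
         call. = FALSE)
  structure(h, variant = variant, shift = shift, class = "opineq_health")
}

#' @export
print.opineq_health <- function(x, ...) {
  cat(sprintf("<opineq health vector: %s variant, shift %.3g, n = %d>\n",
              attr(x, "variant"), attr(x, "shift"), length(x)))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Per-diagnosis cost-variance feature
#'
#' Computes the variance of total medical expenses within each ICD-10
#' diagnosis group, assigns it to every member of the group, and
#' quantile-bins the patient-level values into `n_bins` ordinal codes
#' (0 to `n_bins - 1`). Captures variability of healthcare utilization for
#' patients with the same diagnosis. Groups of size 1 get variance 0 (with a
#' warning).
#'
#' @param records patient records with `total_expenses` and `icd10_group`
#'   (expenses are expected to be winsorized already).
#' @param n_bins number of quantile bins (default 5, coded 0--4).
#' @return Integer vector of bin codes aligned with `records` rows.
#' @export
cost_variance_feature <- function(records, n_bins = 5) {
  stopifnot(is.data.frame(records),
            all(c("total_expenses", "icd10_group") %in% names(records)))
  gv <- records |>
    dplyr::group_by(.data$icd10_group) |>
    dplyr::summarise(.gvar = if (dplyr::n() < 2L) 0 else
      var(.data$total_expenses), .n = dplyr::n())
  if (any(gv$.n == 1L))
    warning("Diagnosis groups of size 1: variance set to 0 by convention.")
  v <- gv$.gvar[match(records$icd10_group, gv$icd10_group)]
  breaks <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7, names = FALSE))
  if (length(breaks) < 2L) return(rep(0L, length(v)))
  cut(v, breaks, include.lowest = TRUE, labels = FALSE) - 1L
}

#' Assemble the environment matrix
#'
#' Builds the analysis covariate table: the 13 environmental variables
#' (demographics, city healthcare resources, admission covariates, and the
#' derived per-diagnosis cost-variance code), winsorizing expenses and
#' mean-imputing along the way. Returns the table together with a
#' preprocessing report.
#'
#' @param records filtered patient records.
#' @param n_bins quantile bins for the cost-variance feature.
#' @param winsor_pct two percentiles for expense winsorization.
#' @return A list with `env` (tibble of 13 covariates), `records` (records
#'   with winsorized expenses) and `report` (named list: winsorization
#'   bounds, imputation counts).
#' @export
build_environment <- function(records, n_bins = 5, winsor_pct = c(1, 99)) {
  stopifnot(is.data.frame(records))
  n_missing <- sum(is.na(records$total_expenses))
  if (n_missing > 0)
    records["total_expenses"] <- impute_means(records["total_expenses"])
  records$total_expenses <- winsorize(records$total_expenses,
                                      winsor_pct[1], winsor_pct[2])
  cols <- c("age", "gender", "ethnicity", "marital_status",
            "occupational_risk", "beds_per_1000", "doctors_per_1000",
            "rail_transit", "old_area", "surgical_level",
            "emergency_admission", "admission_condition")
  miss <- vapply(records[cols], function(x) sum(is.na(x)), numeric(1))
  env <- impute_means(records[cols],
                      leveled = c("occupational_risk", "surgical_level",
                                  "admission_condition"))
  env$cost_variance <- as.numeric(cost_variance_feature(records, n_bins))
  env <- env[, c("age", "gender", "ethnicity", "marital_status",
                 "occupational_risk", "beds_per_1000", "doctors_per_1000",
                 "rail_transit", "old_area", "cost_variance",
                 "surgical_level", "emergency_admission",
                 "admission_condition")]
  list(env = tibble::as_tibble(env), records = records,
       report = list(winsor_bounds = quantile(records$total_expenses,
                                              winsor_pct / 100,
                                              names = FALSE),
                     imputed = c(miss, total_expenses = n_missing)))
}
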