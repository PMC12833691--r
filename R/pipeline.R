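#' Default pipeline configuration
#'
#' Demo-scale run configuration: a synthetic cohort of 20,000 admissions with
#' interaction-type environment effects, both health variants, all three
#' model families, TreeSHAP-surrogate decomposition for the tree models and
#' exact retraining decomposition for the linear model, and quantile
#' analysis at the quartiles and median.
#'
#' @param n cohort size.
#' @param seed root seed; all stochastic stages derive their seeds from it.
#' @param nonlinearity generator DGP shape.
#' @param env_share generator environment share.
#' @return A config list for [run_opineq()].
#' @export
default_run_config <- function(n = 20000, seed = 1,
                               nonlinearity = "interaction",
                               env_share = 0.12) {
  list(
    generator = list(n = n, seed = seed, nonlinearity = nonlinearity,
                     env_share = env_share),
    input_csv = NULL,
    shift = 5,
    variants = c("primary", "composite"),
    split = 0.8,
    models = list(
      linear = list(),
      cit = list(alpha = 0.05, max_depth = 6, min_node = 20),
      forest = list(B = 200, max_depth = 8, min_node = 5)),
    tune = list(enabled = FALSE, grid = 1:20, folds = 5),
    decomposition = list(mode = "auto", exact_limit = 13, n_attrib = 4000),
    taus = c(0.25, 0.5, 0.75),
    seed = seed)
}

# hand-written YAML: a bare `n:` key parses as boolean FALSE (YAML 1.1);
# map it back
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
  lapply(x, fix_yaml_keys)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- fix_yaml_keys(yaml::read_yaml(config))
  base <- default_run_config()
  base[names(config)] <- config
  if (!is.null(base$input_csv) && !is.null(config$generator))
    stop("Config must name exactly one input source (csv or generator).",
         call. = FALSE)
  base
}

fit_family <- function(family, E, H, cfg, seed) {
  args <- cfg$models[[family]] %||% list()
  switch(family,
         linear = fit_linear(E, H),
         cit = do.call(fit_cit, c(list(E = E, H = H, seed = seed), args)),
         forest = do.call(fit_forest, c(list(E = E, H = H, seed = seed),
                                        args)))
}

#' Run the full opportunity-inequality pipeline
#'
#' Orchestrates simulate/load, preprocessing, model fitting (three families
#' by up to two health variants), inequality measurement, Shapley
#' decomposition and per-quantile analysis into one seeded, reproducible
#' run. Produces three report tables: per-model inequality measures
#' (`table1`), per-variable contribution shares (`table3`) and per-quantile
#' results (`table4`).
#'
#' @param config a config list (see [default_run_config()]) or the path of a
#'   YAML file with the same structure.
#' @param out_dir optional output directory; when given, writes
#'   `table1.csv`, `table3.csv`, `table4.csv` and `run-metadata.json`.
#' @return A list with `table1`, `table3`, `table4` tibbles, the fitted
#'   models, and run metadata. Identical configs (and seeds) give identical
#'   outputs.
#' @export
run_opineq <- function(config = default_run_config(), out_dir = NULL) {
  cfg <- read_run_config(config)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("Pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }

  records <- stage("input", {
    if (!is.null(cfg$input_csv)) {
      rec <- tibble::as_tibble(utils::read.csv(cfg$input_csv,
                                               stringsAsFactors = FALSE))
      if ("secondary_dx" %in% names(rec)) {
        rec$secondary_dx <- as.character(rec$secondary_dx)
        rec$secondary_dx[is.na(rec$secondary_dx)] <- ""
      }
      rec
    } else {
      gen <- do.call(generator_config, cfg$generator)
      simulate_patients(gen)
    }
  })

  prep <- stage("preprocess", {
    rec <- filter_study_population(records)
    env <- build_environment(rec)
    rmap <- rint_fit(env$records$primary_dx, levels = 1:4)
    list(env = env, rint = rmap)
  })
  E <- prep$env$env
  recs <- prep$env$records

  variants <- intersect(cfg$variants, c("primary", "composite"))
  table1 <- table3 <- table4 <- list()
  models_out <- list()

  for (variant in variants) {
    H <- make_health(recs, variant, prep$rint, shift = cfg$shift)
    # stratified (by discharge category) train/test split for fit metrics
    set.seed(substream(cfg$seed, "folds"))
    idx_test <- unlist(lapply(split(seq_len(nrow(E)), recs$primary_dx),
                              function(ix) sample(ix, round((1 - cfg$split) *
                                                              length(ix)))))
    tr <- setdiff(seq_len(nrow(E)), idx_test)
    for (family in names(cfg$models)) {
      key <- paste(variant, family, sep = ".")
      seed_f <- substream(cfg$seed, "models")
      depth <- cfg$models[[family]]$max_depth
      if (isTRUE(cfg$tune$enabled) && family != "linear") {
        depth <- as.integer(tune_depth(family, E[tr, ], H[tr],
                                       grid = cfg$tune$grid,
                                       folds = cfg$tune$folds,
                                       seed = seed_f))
        cfg$models[[family]]$max_depth <- depth
      }
      m_train <- stage(paste0("fit_train.", key),
                       fit_family(family, E[tr, ], H[tr], cfg, seed_f))
      perf <- evaluate(m_train, E[idx_test, ], H[idx_test])
      m_full <- stage(paste0("fit_full.", key),
                      fit_family(family, E, H, cfg, seed_f))
      iop <- opportunity_inequality(m_full, H)
      models_out[[key]] <- m_full
      table1[[key]] <- tibble::tibble(
        variant = variant, family = family,
        absolute_iop = iop$absolute_iop, relative_iop = iop$relative_iop,
        total_mld = iop$total_mld,
        depth = if (family == "linear") NA_real_ else as.numeric(depth),
        mse = perf$mse, r2 = perf$r2,
        oob_error = m_full$diagnostics$oob_error)

      mode <- cfg$decomposition$mode
      contrib <- stage(paste0("decompose.", key), {
        if (mode == "exact" || (mode == "auto" && family == "linear")) {
          recipe <- switch(family,
                           linear = model_recipe("linear"),
                           cit = do.call(model_recipe,
                                         c(list("cit"),
                                           cfg$models$cit,
                                           list(seed = seed_f))),
                           forest = do.call(model_recipe,
                                            c(list("forest"),
                                              utils::modifyList(
                                                cfg$models$forest,
                                                list(B = 100)),
                                              list(seed = seed_f))))
          shapley_exact(E, H, recipe,
                        exact_limit = cfg$decomposition$exact_limit)
        } else {
          # tree attributions are computed on a seeded subsample: the
          # surrogate coalition values are MLDs, estimated well at a few
          # thousand rows for a fraction of the TreeSHAP cost
          n_attrib <- cfg$decomposition$n_attrib %||% nrow(E)
          rows <- if (nrow(E) > n_attrib) {
            set.seed(substream(cfg$seed, "shapley"))
            sort(sample(nrow(E), n_attrib))
          } else seq_len(nrow(E))
          surrogate_inequality_shares(
            attribution_matrix(m_full, E[rows, , drop = FALSE],
                               background = E))
        }
      })
      table3[[key]] <- dplyr::mutate(tibble::as_tibble(contrib),
                                     variant = variant, family = family,
                                     method = attr(contrib, "method"),
                                     .before = 1)
    }
    q <- stage(paste0("quantile.", variant),
               quantile_iop(E, H, taus = cfg$taus, on_degenerate = "na"))
    table4[[variant]] <- dplyr::left_join(
      dplyr::mutate(q$summary, variant = variant, .before = 1),
      dplyr::mutate(
        tidyr::pivot_wider(q$contributions[, c("tau", "variable", "share")],
                           names_from = "variable", values_from = "share"),
        variant = variant, .before = 1),
      by = c("variant", "tau"))
  }

  out <- list(table1 = dplyr::bind_rows(table1),
              table3 = dplyr::bind_rows(table3),
              table4 = dplyr::bind_rows(table4),
              models = models_out,
              rint = prep$rint,
              meta = list(seed = cfg$seed, shift = cfg$shift,
                          n = nrow(E), variants = variants,
                          timings = timings,
                          preprocess = prep$env$report,
                          package_version =
                            as.character(utils::packageVersion("opineq")),
                          finished = format(t0, "%Y-%m-%d %H:%M:%S")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$table1, file.path(out_dir, "table1.csv"),
              row.names = FALSE)
    write.csv(out$table3, file.path(out_dir, "table3.csv"),
              row.names = FALSE)
    write.csv(out$table4, file.path(out_dir, "table4.csv"),
              row.names = FALSE)
    jsonlite::write_json(out$meta, file.path(out_dir, "run-metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
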