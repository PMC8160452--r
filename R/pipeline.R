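# End-to-end experiment orchestration, wiring the stages into the study
# shape: simulate sites -> exclusions -> subgroup reference -> preprocessing
# -> stratified split -> screening and spline design -> Models 1-3 (plus
# panel-restricted variants retrained for each external site) -> internal and
# external validation reports.

#' Build a full pipeline configuration
#'
#' All randomness is derived deterministically from `seed`; rerunning the
#' same configuration reproduces every output.
#'
#' @param seed master seed.
#' @param n_internal internal (derivation) cohort size.
#' @param n_external per-site external cohort size.
#' @param bootstrap_replicates bootstrap replicates for every CI.
#' @param external named list of external site descriptors
#'   (`list(shift = site_shift(...), max_collection_hours = 72)`), or `NULL`
#'   for the two default sites: one with completed-weeks GA reporting and a
#'   slightly reduced panel, one lacking the hemoglobin fractions with
#'   delayed collection and inflated analyte dispersion.
#' @param l1_fractions,n_lambda elastic-net hyperparameter grid.
#' @param top_k number of screened analytes modelled with splines.
#' @param scaling `"local"` (refit fences/scaling per cohort) or
#'   `"training"` (reuse the derivation-cohort parameters).
#' @param internal_config optional [synthetic_config()] overriding the
#'   default internal generator.
#' @param split sub-cohort fractions.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L,
                            n_internal = 20000,
                            n_external = 5000,
                            bootstrap_replicates = 1000,
                            external = NULL,
                            l1_fractions = c(0.1, 0.5, 0.9),
                            n_lambda = 50,
                            top_k = 7,
                            scaling = c("local", "training"),
                            internal_config = NULL,
                            split = c(development = 0.5, validation = 0.25,
                                      test = 0.25)) {
  scaling <- match.arg(scaling)
  seed <- as.integer(seed)
  if (is.null(internal_config)) {
    internal_config <- synthetic_config(n_infants = n_internal, seed = seed,
                                        site_label = "internal")
  }
  full_panel <- internal_config$analyte_panel
  if (is.null(external)) {
    external <- list(
      siteB = list(
        shift = site_shift("siteB",
                           panel = setdiff(full_panel, c("GALT", "SUAC")),
                           multiplicative_bias = 1.1,
                           additive_log_shift = 0.1,
                           dispersion_factor = 1.15,
                           collection_delay_hours = 6,
                           ga_reporting = "completed_weeks"),
        max_collection_hours = 72),
      siteC = list(
        shift = site_shift("siteC",
                           panel = setdiff(full_panel,
                                           c(hemoglobin_columns, "GALT",
                                             "BIO", "IRT", "SUAC")),
                           multiplicative_bias = 0.9,
                           additive_log_shift = -0.05,
                           dispersion_factor = 1.2,
                           collection_delay_hours = 24,
                           ga_reporting = "decimal_weeks"),
        max_collection_hours = 72)
    )
  }
  ext <- external
  for (i in seq_along(ext)) {
    if (is.null(ext[[i]]$synthetic)) {
      ext[[i]]$synthetic <- synthetic_config(
        n_infants = n_external, seed = seed + 1000L * i,
        site_label = names(ext)[i])
    }
    if (is.null(ext[[i]]$max_collection_hours)) {
      ext[[i]]$max_collection_hours <- 72
    }
    ext[[i]]$shift_seed <- seed + 7000L + i
  }
  list(seed = seed, internal = internal_config,
       max_collection_hours_internal = 48,
       external = ext, split = split, split_seed = seed + 31L,
       l1_fractions = l1_fractions, n_lambda = n_lambda, top_k = top_k,
       scaling = scaling, bootstrap_replicates = bootstrap_replicates,
       bootstrap_seed = seed + 53L)
}

# Fit Models 1-3 on prepared development/validation designs.
.fit_three_models <- function(specs, dev, val, dev_ga, val_ga, config,
                              preprocess_ref) {
  models <- list()
  paths <- list()
  d1 <- build_design_matrix(dev, specs$model1)
  models$model1 <- fit_baseline_model(d1, dev_ga, spec = specs$model1,
                                      preprocess_ref = preprocess_ref)
  for (nm in c("model2", "model3")) {
    dd <- build_design_matrix(dev, specs[[nm]])
    dv <- build_design_matrix(val, specs[[nm]])
    pp <- select_hyperparameters(dd, dev_ga, dv, val_ga,
                                 l1_fractions = config$l1_fractions,
                                 n_lambda = config$n_lambda)
    models[[nm]] <- fit_elastic_net(dd, dev_ga,
                                    l1_fraction = pp$chosen$l1_fraction,
                                    penalty_strength = pp$chosen$penalty_strength,
                                    spec = specs[[nm]],
                                    preprocess_ref = preprocess_ref)
    paths[[nm]] <- pp
  }
  list(models = models, penalty_paths = paths)
}

#' Run the full estimation and validation pipeline
#'
#' @param config from [pipeline_config()].
#' @param outdir directory for artifacts (cohort CSVs, preprocessing
#'   parameters, screening table, fitted models, penalty paths, validation
#'   reports, run log), or `NULL` to skip writing.
#' @return (invisibly) list with the fitted models, screening table, internal
#'   and external validation reports, and intermediate cohorts.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- internal cohort -----------------------------------------------------
  say("simulating internal cohort (n = %d)", config$internal$n_infants)
  raw_internal <- generate_cohort(config$internal)
  excl <- apply_exclusions(raw_internal, config$max_collection_hours_internal)
  say("internal exclusions: late=%d screen_positive=%d missing=%d retained=%d",
      excl$log[["late_collection"]], excl$log[["screen_positive"]],
      excl$log[["missing_field"]], excl$log[["retained"]])
  internal <- excl$cohort
  ref_pct <- compute_bw_percentiles(internal)
  internal <- classify_subgroups(internal, ref_pct)
  prep <- preprocess_cohort(internal, label = "internal")
  internal_pp <- prep$cohort
  params_internal <- prep$params

  subs <- split_cohort(internal_pp, config$split, seed = config$split_seed)
  dev <- subs$development; val <- subs$validation; test <- subs$test
  say("split: dev=%d val=%d test=%d", nrow(dev), nrow(val), nrow(test))

  # --- screening and specs -------------------------------------------------
  candidates <- modeling_analytes(dev)
  screen <- partial_spearman_screen(dev, candidates, top_k = config$top_k)
  top <- attr(screen, "top_k")
  say("screened top-%d analytes: %s", config$top_k, paste(top, collapse = ", "))

  knots_for <- function(data, vars) {
    stats::setNames(lapply(vars, function(v) compute_knots(data[[v]])), vars)
  }
  bw_knots <- knots_for(dev, "birth_weight_g")
  top_knots <- knots_for(dev, top)
  specs <- list(
    model1 = model_spec(1, "birth_weight_g", bw_knots,
                        interactions = "sex_by_spline", top_k_splined = 0),
    model2 = model_spec(2, candidates, top_knots,
                        top_k_splined = length(top)),
    model3 = model_spec(3, c("birth_weight_g", candidates),
                        c(bw_knots, top_knots),
                        top_k_splined = length(top))
  )

  say("fitting models 1-3 on the development sub-cohort")
  fit <- .fit_three_models(specs, dev, val, dev$ga_weeks, val$ga_weeks,
                           config, preprocess_ref = "internal")

  # --- internal validation -------------------------------------------------
  say("internal test-set validation (B = %d)", config$bootstrap_replicates)
  internal_reports <- list()
  predictions <- list(internal = list())
  for (nm in names(fit$models)) {
    est <- predict_ga(fit$models[[nm]], test)
    predictions$internal[[nm]] <- data.frame(id = test$id,
                                             ga_ref = test$ga_weeks,
                                             ga_est = est)
    internal_reports[[nm]] <- build_validation_report(
      test, est, n_replicates = config$bootstrap_replicates,
      seed = config$bootstrap_seed, completed_weeks = FALSE,
      cohort_label = paste0("internal_test_", nm))
  }

  # --- external sites ------------------------------------------------------
  external_reports <- list()
  external_models <- list()
  external_cohorts <- list()
  for (site in names(config$external)) {
    ext_cfg <- config$external[[site]]
    say("external site '%s': simulate, shift, validate", site)
    raw <- generate_cohort(ext_cfg$synthetic)
    shifted <- apply_site_shift(raw, ext_cfg$shift, seed = ext_cfg$shift_seed)
    e <- apply_exclusions(shifted, ext_cfg$max_collection_hours)
    say("  exclusions: late=%d screen_positive=%d missing=%d retained=%d",
        e$log[["late_collection"]], e$log[["screen_positive"]],
        e$log[["missing_field"]], e$log[["retained"]])
    ext <- classify_subgroups(e$cohort, ref_pct)
    if (config$scaling == "local") {
      ext_pp <- preprocess_cohort(ext, label = site)$cohort
    } else {
      ext_pp <- preprocess_cohort(ext, params = params_internal)$cohort
    }
    avail <- modeling_analytes(ext_pp)
    site_models <- list(model1 = fit$models$model1)
    for (nm in c("model2", "model3")) {
      rspec <- restrict_model_spec(specs[[nm]], avail)
      if (identical(rspec$quantitative, specs[[nm]]$quantitative)) {
        site_models[[nm]] <- fit$models[[nm]]
      } else {
        say("  retraining restricted %s (%d splined analytes)", nm,
            rspec$top_k_splined)
        dd <- build_design_matrix(dev, rspec)
        dv <- build_design_matrix(val, rspec)
        pp <- select_hyperparameters(dd, dev$ga_weeks, dv, val$ga_weeks,
                                     l1_fractions = config$l1_fractions,
                                     n_lambda = config$n_lambda)
        site_models[[nm]] <- fit_elastic_net(
          dd, dev$ga_weeks, l1_fraction = pp$chosen$l1_fraction,
          penalty_strength = pp$chosen$penalty_strength, spec = rspec,
          preprocess_ref = "internal")
      }
    }
    external_models[[site]] <- site_models
    external_cohorts[[site]] <- ext_pp
    reports <- list()
    predictions[[site]] <- list()
    for (nm in names(site_models)) {
      est <- predict_ga(site_models[[nm]], ext_pp, check_scaling = FALSE)
      predictions[[site]][[nm]] <- data.frame(id = ext_pp$id,
                                              ga_ref = ext_pp$ga_weeks,
                                              ga_est = est)
      reports[[nm]] <- build_validation_report(
        ext_pp, est, n_replicates = config$bootstrap_replicates,
        seed = config$bootstrap_seed,
        completed_weeks = ext_cfg$shift$ga_reporting == "completed_weeks",
        cohort_label = paste0(site, "_", nm))
    }
    external_reports[[site]] <- reports
  }

  result <- list(config = config,
                 exclusion_log_internal = excl$log,
                 reference_percentiles = ref_pct,
                 preprocess_params = params_internal,
                 screening = screen,
                 specs = specs,
                 models = fit$models,
                 penalty_paths = fit$penalty_paths,
                 internal_reports = internal_reports,
                 external_models = external_models,
                 external_reports = external_reports,
                 predictions = predictions,
                 cohorts = list(internal_test = test,
                                internal_development = dev,
                                internal_validation = val,
                                external = external_cohorts))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(raw_internal, file.path(outdir, "cohort_internal_raw.csv"))
    write_preprocess_params(params_internal,
                            file.path(outdir, "preprocess_params_internal.json"))
    utils::write.csv(ref_pct, file.path(outdir, "bw_reference_percentiles.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(outdir, "screening.csv"),
                     row.names = FALSE)
    for (nm in names(fit$models)) {
      write_ga_model(fit$models[[nm]], file.path(outdir, paste0(nm, ".json")))
    }
    for (nm in names(fit$penalty_paths)) {
      utils::write.csv(fit$penalty_paths[[nm]]$grid,
                       file.path(outdir, paste0("penalty_path_", nm, ".csv")),
                       row.names = FALSE)
    }
    for (nm in names(internal_reports)) {
      write_validation_report(internal_reports[[nm]],
                              file.path(outdir, paste0("report_internal_", nm,
                                                       ".json")))
      utils::write.csv(as.data.frame(internal_reports[[nm]]),
                       file.path(outdir, paste0("report_internal_", nm, ".csv")),
                       row.names = FALSE)
    }
    for (site in names(external_reports)) {
      for (nm in names(external_reports[[site]])) {
        write_validation_report(
          external_reports[[site]][[nm]],
          file.path(outdir, sprintf("report_%s_%s.json", site, nm)))
        utils::write.csv(
          as.data.frame(external_reports[[site]][[nm]]),
          file.path(outdir, sprintf("report_%s_%s.csv", site, nm)),
          row.names = FALSE)
      }
    }
    log_lines <- c(log_lines,
                   sprintf("R version: %s", R.version.string),
                   sprintf("seed: %d", config$seed),
                   sprintf("elapsed: %.1f s",
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  invisible(result)
}
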