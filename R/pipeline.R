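#' Configuration of the end-to-end pipeline
#'
#' Collects the settings of every stage. All randomness in a pipeline run
#' derives from the single `seed`: the generator, split-sampling, forests,
#' importance permutations and bootstrap each get a fixed offset of it.
#'
#' @param seed master integer seed.
#' @param generator named list of [generator_config()] overrides (its
#'   `seed` defaults to the master seed).
#' @param covariates list: `substitution_threshold` (marina exposure
#'   substitution, default 10000), `attenuation_k` (per metre, default 0.5).
#' @param occurrence list: `families`, `n_splits` (100), `train_frac` (0.8),
#'   `auc_min` (0.70), `tss_min` (0.50), plus [fit_committee()] `control`
#'   entries.
#' @param abundance list: `folds` (6), `repeats` (10), `ntree` (500).
#' @param projection list: `n_marinas` (54), `n_natural` (108), `n_boot`
#'   (1000), `level` (0.95).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, generator = list(), covariates = list(),
                            occurrence = list(), abundance = list(),
                            projection = list()) {
  if (is.null(generator$seed)) generator$seed <- seed
  structure(list(
    seed = as.integer(seed),
    generator = do.call(generator_config, generator),
    covariates = utils::modifyList(
      list(substitution_threshold = 10000, attenuation_k = 0.5), covariates),
    occurrence = utils::modifyList(
      list(families = c("glm", "gam", "gbm", "rf"), n_splits = 100,
           train_frac = 0.8, auc_min = 0.70, tss_min = 0.50), occurrence),
    abundance = utils::modifyList(
      list(folds = 6, repeats = 10, ntree = 500), abundance),
    projection = utils::modifyList(
      list(n_marinas = 54, n_natural = 108, n_boot = 1000, level = 0.95),
      projection)),
    class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Prepare model covariates from raw site values
#'
#' Applies the marina exposure substitution (breakwater correction) and the
#' depth attenuation, in that order, returning the table with `exposure`
#' replaced by its prepared value. Used identically for training and
#' projection sites.
#'
#' @param sites table with `habitat_type`, `exposure`, `depth`.
#' @param threshold marina substitution threshold.
#' @param k attenuation coefficient per metre.
#' @return `sites` with prepared `exposure`.
#' @export
prepare_covariates <- function(sites, threshold = 10000, k = 0.5) {
  is_marina <- sites$habitat_type == "marina"
  if (any(is_marina))
    sites$exposure[is_marina] <-
      substitute_marina_exposure(sites$exposure[is_marina], threshold)
  depth <- if ("depth" %in% names(sites)) sites$depth else 0.5
  sites$exposure <- attenuate_exposure(sites$exposure, depth, k)
  sites
}

#' Run the full invasion-risk pipeline
#'
#' Executes, in order: synthetic survey generation (unless tables are
#' supplied), covariate preparation and collinearity screening, the
#' field summary (site abundance, habitat ANOVA), the gated occurrence
#' ensemble, the bias-corrected abundance model, predictor influence for
#' both models, and the habitat-stratified projection with bootstrap
#' intervals. Identical config and seed give identical outputs; any stage
#' error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param survey optional list(sites, quadrats) to use instead of
#'   simulating.
#' @param projection optional projection-site table; `FALSE` skips the
#'   projection/estimation stages (fit-only run).
#' @param out_dir optional directory: writes sites.csv, quadrats.csv,
#'   projection.csv, estimates.csv, importance and response-curve CSVs, and
#'   manifest.json.
#' @return List with all artifacts: `survey`, `screen`, `field`,
#'   `ensemble`, `abundance`, `influence`, `projected`, `estimates`,
#'   `per_unit`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), survey = NULL,
                         projection = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator

  survey <- run_stage("simulate", {
    if (is.null(survey)) generate_survey(gen) else survey
  })
  sites <- survey$sites; quadrats <- survey$quadrats

  sites <- run_stage("covariates", prepare_covariates(
    sites, config$covariates$substitution_threshold,
    config$covariates$attenuation_k))
  screen <- run_stage("covariates", collinearity_screen(
    sites[c("substrate_cover", "min_salinity", "exposure")]))
  message(sprintf("[covariates] max |r| = %.2f, max VIF = %.2f",
                  max(abs(screen$correlation[upper.tri(screen$correlation)])),
                  max(screen$vif)))

  field <- run_stage("field_summary", {
    ab <- site_abundance_table(quadrats, sites, gen$quadrat_area)
    occupied <- ab[ab$abundance > 0, ]
    cmp <- if (length(unique(occupied$habitat_type)) >= 2 &&
               all(table(occupied$habitat_type) >= 2))
      habitat_comparison(occupied$abundance, occupied$habitat_type) else NULL
    list(site_abundance = ab, comparison = cmp)
  })

  ensemble <- run_stage("occurrence", {
    first <- quadrats[quadrats$is_first, c("site_id", "substrate_cover")]
    occ_tab <- merge(sites[c("site_id", "min_salinity", "exposure", "presence")],
                     first, by = "site_id", sort = FALSE)
    committee <- suppressWarnings(fit_committee(
      occ_tab, predictors = c("substrate_cover", "min_salinity", "exposure"),
      families = config$occurrence$families,
      n_splits = config$occurrence$n_splits,
      train_frac = config$occurrence$train_frac,
      seed = config$seed + 1L))
    build_ensemble(committee, config$occurrence$auc_min,
                   config$occurrence$tss_min)
  })
  message(sprintf("[occurrence] included %.0f%%; calibration AUC = %.3f; cutoff = %.3f",
                  100 * ensemble$inclusion_fraction, ensemble$calibration_auc,
                  ensemble$cutoff))

  abundance <- run_stage("abundance", {
    site_sub <- stats::aggregate(substrate_cover ~ site_id, quadrats, mean)
    ab_tab <- merge(sites[c("site_id", "min_salinity", "exposure", "presence")],
                    site_sub, by = "site_id", sort = FALSE)
    ab_tab <- merge(ab_tab, field$site_abundance[c("site_id", "abundance")],
                    by = "site_id", sort = FALSE)
    ab_tab <- ab_tab[ab_tab$presence & ab_tab$abundance > 0, ]
    fit_abundance(ab_tab,
                  predictors = c("substrate_cover", "min_salinity", "exposure"),
                  folds = config$abundance$folds,
                  repeats = config$abundance$repeats,
                  ntree = config$abundance$ntree,
                  seed = config$seed + 2L)
  })
  message(sprintf("[abundance] CV RMSE = %.3f; smearing S = %.3f",
                  abundance$cv_rmse, abundance$smearing))

  influence <- run_stage("influence", {
    first <- quadrats[quadrats$is_first, c("site_id", "substrate_cover")]
    occ_tab <- merge(sites[c("site_id", "min_salinity", "exposure")],
                     first, by = "site_id", sort = FALSE)
    pres <- sites$presence
    ab_data <- occ_tab[pres, , drop = FALSE]
    vars <- c("substrate_cover", "min_salinity", "exposure")
    list(
      occurrence_importance = permutation_importance(
        ensemble, occ_tab, vars, seed = config$seed + 3L),
      abundance_importance = permutation_importance(
        abundance, ab_data, vars, seed = config$seed + 3L),
      occurrence_curves = lapply(stats::setNames(vars, vars), function(v)
        response_curve(ensemble, v, occ_tab)),
      abundance_curves = lapply(stats::setNames(vars, vars), function(v)
        response_curve(abundance, v, ab_data)))
  })

  projected <- estimates <- per_unit <- NULL
  if (isFALSE(projection)) {
    message("[projection] no projection table supplied; estimation stage skipped")
  } else {
    projected <- run_stage("projection", {
      proj <- if (is.null(projection))
        generate_projection_set(gen, config$projection$n_marinas,
                                config$projection$n_natural)
      else projection
      proj <- prepare_covariates(proj, config$covariates$substitution_threshold,
                                 config$covariates$attenuation_k)
      project_sites(ensemble, abundance, proj)
    })
    estimates <- run_stage("estimation", habitat_estimates(
      projected,
      length_freqs = list(marina = length_class_freqs(gen, "marina"),
                          natural_rocky = length_class_freqs(gen, "natural_rocky")),
      n_boot = config$projection$n_boot, level = config$projection$level,
      seed = config$seed + 4L))
    per_unit <- run_stage("estimation", per_unit_area(estimates))
    message(sprintf("[estimation] per-unit-area abundance ratio marina:natural_rocky = %.1f",
                    per_unit$abundance_ratio))
  }

  manifest <- list(
    package = "oysterfront",
    version = as.character(utils::packageVersion("oysterfront")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = c(generator = gen$seed, committee = config$seed + 1L,
                    abundance = config$seed + 2L, influence = config$seed + 3L,
                    bootstrap = config$seed + 4L),
    n_sites = nrow(sites),
    metrics = list(
      calibration_auc = ensemble$calibration_auc,
      cutoff = ensemble$cutoff,
      inclusion_fraction = ensemble$inclusion_fraction,
      cv_rmse = abundance$cv_rmse,
      smearing = abundance$smearing))

  result <- list(survey = list(sites = sites, quadrats = quadrats),
                 screen = screen, field = field, ensemble = ensemble,
                 abundance = abundance, influence = influence,
                 projected = projected, estimates = estimates,
                 per_unit = per_unit, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  # run finalizers for native model handles (forests, boosters) from any
  # previous, now-unreferenced run; they are invisible to R's heap counters
  gc(verbose = FALSE)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_survey(result$survey, out_dir)
  utils::write.csv(result$field$site_abundance,
                   file.path(out_dir, "site_abundance.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$influence$occurrence_importance),
                   file.path(out_dir, "importance_occurrence.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$influence$abundance_importance),
                   file.path(out_dir, "importance_abundance.csv"),
                   row.names = FALSE)
  for (side in c("occurrence", "abundance")) {
    curves <- result$influence[[paste0(side, "_curves")]]
    for (v in names(curves))
      utils::write.csv(as.data.frame(curves[[v]]),
                       file.path(out_dir, sprintf("curve_%s_%s.csv", side, v)),
                       row.names = FALSE)
  }
  if (!is.null(result$projected))
    write_projection(result$projected, file.path(out_dir, "projection.csv"))
  if (!is.null(result$estimates))
    utils::write.csv(as.data.frame(result$estimates),
                     file.path(out_dir, "estimates.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
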