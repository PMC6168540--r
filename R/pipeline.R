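#' Configuration for an end-to-end synthetic run
#'
#' Bundles every knob of the pipeline with defaults mirroring the shape of
#' the study design: 40 eco-regions, a 27-year calibration window
#' (1985-2011), a 1971-2000 reference period, the 3/6/12-month by
#' March-September candidate grid, 1000 bootstrap replicates, 9 members per
#' scenario, and the 1.5/2/3 degree warming levels. Every stochastic stage
#' receives a sub-seed derived from `seed`.
#'
#' @param n_regions number of eco-regions.
#' @param start_year,end_year observed-panel span.
#' @param calibration_years burned-area calibration window.
#' @param reference_period reference window (SPEI standardization, bias
#'   correction, percent-change baseline).
#' @param scales,months candidate SPEI grid.
#' @param alpha FDR / significance level.
#' @param B bootstrap and permutation replicates.
#' @param levels warming levels (degrees C).
#' @param covariate non-stationary-model covariate.
#' @param policy extrapolation policy.
#' @param nsm_mode reference-side convention of the NSM, see [project_nsm()].
#' @param bias_correct logical, linear-scaling correction of members.
#' @param climate a [climate_config()].
#' @param rcm an [rcm_config()].
#' @param truth_args extra arguments passed to [simulate_truth()].
#' @param weights optional region weights for spatial averaging.
#' @param seed master seed.
#' @return List of class `run_config`.
#' @export
fire_run_config <- function(n_regions = 40, start_year = 1950, end_year = 2015,
                            calibration_years = 1985:2011,
                            reference_period = c(1971, 2000),
                            scales = c(3, 6, 12), months = 3:9,
                            alpha = 0.05, B = 1000,
                            levels = c(1.5, 2, 3), covariate = "Ty",
                            policy = "extrapolate", nsm_mode = "future_only",
                            bias_correct = TRUE,
                            climate = climate_config(), rcm = rcm_config(),
                            truth_args = list(), weights = NULL, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full climate-fire modelling chain on synthetic data
#'
#' Stages, in order: synthesize the observed climate panel; plant the ground
#' truth and generate burned area; simulate the pseudo-RCM ensemble;
#' calibrate the per-region drought-fire models; fit and rank the
#' cross-region drought-sensitivity models; find warming windows and project
#' percent burned-area changes with the stationary and non-stationary
#' variants; summarise the ensemble and classify regions. Each stage draws
#' its own sub-seed from `config$seed`, so a run is reproducible end to end.
#'
#' @param config a [fire_run_config()].
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV and the manifest as JSON.
#' @return List of class `fire_run` with elements `config`, `climate`,
#'   `truth`, `ba`, `fits`, `beta2_models`, `ranking`, `beta2_model`,
#'   `ensemble`, `projection`, `summaries`, `classification`, `windows`,
#'   `manifest`.
#' @export
run_fire_pipeline <- function(config = fire_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  climate <- simulate_climate(config$n_regions, config$start_year,
                              config$end_year, seed = derive_seed(seed, 11),
                              config = config$climate)
  truth <- do.call(simulate_truth, c(
    list(climate = climate, seed = derive_seed(seed, 12),
         normal_window = config$reference_period), config$truth_args))
  ba <- simulate_burned_area(climate, truth,
                             reference_period = config$reference_period,
                             seed = derive_seed(seed, 13)) %>%
    dplyr::filter(.data$year %in% config$calibration_years)
  ensemble <- simulate_rcm_ensemble(climate, config = config$rcm,
                                    seed = derive_seed(seed, 14))
  fits <- calibrate_fire_models(
    ba, climate, scales = config$scales, months = config$months,
    reference_period = config$reference_period,
    calibration_years = config$calibration_years,
    B = config$B, alpha = config$alpha, seed = derive_seed(seed, 15))
  normals <- compute_normals(climate, config$reference_period)
  covars <- c("Ty", "Ts", "PREy", "PREs", "P_PETy", "P_PETs")
  beta2_models <- purrr::map(covars, function(cv) {
    fit_beta2_model(fits, normals, covariate = cv, nboot = config$B,
                    seed = derive_seed(seed, 16))
  })
  names(beta2_models) <- covars
  ranking <- rank_beta2_models(beta2_models, alpha = config$alpha)
  chosen_cov <- if (config$covariate %in% ranking$covariate[ranking$retained])
    config$covariate else ranking$covariate[1]
  beta2_model <- beta2_models[[chosen_cov]]
  projection <- project_burned_area(
    fits, ensemble, climate, beta2_model = beta2_model,
    levels = config$levels, variant = c("sm", "nsm"),
    policy = config$policy, reference_period = config$reference_period,
    bias_correct = config$bias_correct, nsm_mode = config$nsm_mode)
  if (nrow(projection) > 0) {
    summaries <- projection %>%
      dplyr::group_by(.data$level, .data$variant) %>%
      dplyr::group_modify(function(df, key) {
        dplyr::bind_rows(
          ensemble_summary(df, weights = config$weights, mode = "rcm"),
          ensemble_summary(df, weights = config$weights, mode = "all"))
      }) %>%
      dplyr::ungroup()
    classification <- projection %>%
      dplyr::filter(.data$replicate > 0) %>%
      dplyr::group_by(.data$level, .data$variant) %>%
      dplyr::group_modify(function(df, key) classify_regions(df)) %>%
      dplyr::ungroup()
  } else {
    # no member reached any requested warming level
    summaries <- tibble::tibble(level = numeric(0), variant = character(0),
                                mode = character(0), n_sim = integer(0),
                                median = numeric(0), q25 = numeric(0),
                                q75 = numeric(0), q025 = numeric(0),
                                q975 = numeric(0))
    classification <- tibble::tibble(level = numeric(0), variant = character(0),
                                     region = character(0), n_sim = integer(0),
                                     frac_significant = numeric(0),
                                     agreement = numeric(0), class = character(0))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("medfire")),
    seed = seed,
    stage_seeds = setNames(
      purrr::map_int(11:16, function(o) derive_seed(seed, o)),
      c("climate", "truth", "burned_area", "ensemble", "calibration",
        "spatial_model")),
    n_regions = config$n_regions,
    n_modelled = sum(fits$modelled),
    calibration_years = range(config$calibration_years),
    reference_period = config$reference_period,
    levels = config$levels, B = config$B, alpha = config$alpha,
    covariate = chosen_cov, policy = config$policy,
    nsm_mode = config$nsm_mode, bias_correct = config$bias_correct)
  run <- structure(list(
    config = config, climate = climate, truth = truth, ba = ba,
    fits = fits, beta2_models = beta2_models, ranking = ranking,
    beta2_model = beta2_model, ensemble = ensemble,
    projection = projection, summaries = summaries,
    classification = classification,
    windows = attr(projection, "windows"), manifest = manifest),
    class = "fire_run")
  if (!is.null(out_dir)) write_fire_run(run, out_dir)
  run
}

#' Write the result tables of a pipeline run
#'
#' @param run a `fire_run` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fire_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$ba, file.path(out_dir, "burned_area.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$fits),
                   file.path(out_dir, "fire_model_fits.csv"), row.names = FALSE)
  utils::write.csv(run$ranking, file.path(out_dir, "beta2_model_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summaries, file.path(out_dir, "change_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(run$classification,
                   file.path(out_dir, "region_classification.csv"),
                   row.names = FALSE)
  utils::write.csv(run$windows, file.path(out_dir, "warming_windows.csv"),
                   row.names = FALSE)
  utils::write.csv(run$truth$coefs, file.path(out_dir, "synthetic_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    run$truth[c("sc", "m", "noise_sd", "gamma", "normal_window")],
    file.path(out_dir, "synthetic_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.fire_run <- function(x, ...) {
  cat(sprintf("fire_run: %d regions (%d modelled), seed %s\n",
              x$manifest$n_regions, x$manifest$n_modelled,
              format(x$manifest$seed)))
  cat(sprintf("NSM covariate: %s; policy: %s\n", x$manifest$covariate,
              x$manifest$policy))
  print(x$summaries)
  invisible(x)
}
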