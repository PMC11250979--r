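# End-to-end orchestration: simulate or ingest -> reconstruct strata ->
# fit the selection model -> weight the cohort -> run the three model
# iterations -> optional misspecification sweep, with persisted artifacts
# and a deterministic run manifest.

#' Configuration for an end-to-end analysis run
#'
#' @param mode `"synthetic"` (generate the population, its external-style
#'   summary and the hospitalised cohort) or `"user-data"` (read summary
#'   and cohort CSVs).
#' @param summary_path,cohort_path CSV paths (user-data mode); see
#'   [read_summary_csv()] and [read_cohort_csv()] for the headers.
#' @param model_form `"eq1"` (wave-1 analysis) or `"eq2"` (two waves with
#'   wave terms in the selection model).
#' @param hospitalised_death_fraction Assumed P(hospitalised | died) used
#'   to split marginal counts (default 0.90).
#' @param sensitivity Run the misspecification sweep in
#'   [run_sensitivity()].
#' @param scenario_grid_path Optional YAML overriding the packaged grid.
#' @param invalid_policy What to do when a shifted parameter set predicts a
#'   probability outside (0, 1]: `"skip"` the scenario (default), `"clip"`
#'   probabilities at 1, or `"shrink"` the shift to the largest valid
#'   multiple.
#' @param simulation A [simulation_config()] (synthetic mode).
#' @param seed Top-level integer seed; in synthetic mode it overrides the
#'   simulation config's seed so all randomness flows from one place.
#' @param output_dir Directory for persisted artifacts (`NULL` keeps
#'   everything in memory).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("synthetic", "user-data"),
                            summary_path = NULL, cohort_path = NULL,
                            model_form = c("eq1", "eq2"),
                            hospitalised_death_fraction = 0.90,
                            sensitivity = FALSE,
                            scenario_grid_path = NULL,
                            invalid_policy = c("skip", "clip", "shrink"),
                            simulation = NULL,
                            seed = NULL,
                            output_dir = NULL) {
  mode <- match.arg(mode)
  model_form <- match.arg(model_form)
  invalid_policy <- match.arg(invalid_policy)
  if (mode == "user-data") {
    for (p in c(summary_path, cohort_path)) {
      if (is.null(p) || !file.exists(p)) {
        cpw_config_error("user-data mode requires existing `summary_path` and `cohort_path`.")
      }
    }
  }
  structure(
    list(
      mode = mode, summary_path = summary_path, cohort_path = cohort_path,
      model_form = model_form,
      hospitalised_death_fraction = hospitalised_death_fraction,
      sensitivity = sensitivity, scenario_grid_path = scenario_grid_path,
      invalid_policy = invalid_policy,
      simulation = simulation %||% simulation_config(),
      seed = seed, output_dir = output_dir
    ),
    class = "analysis_config"
  )
}

#' Run the full collider-correction analysis
#'
#' Executes the stage chain: obtain the marginal summary and hospitalised
#' cohort (simulated or read from disk), reconstruct survival-status strata
#' under the hospitalised-death-fraction assumption, fit the saturated
#' selection model, attach inverse probability weights, and fit the three
#' Cox model iterations. Under `"eq1"` the analysis is restricted to wave 1
#' (the single-wave model); `"eq2"` uses both waves.
#'
#' When `output_dir` is set, every intermediate artifact is persisted
#' (summary, strata, parameters, weighted cohort, hazard-ratio summary)
#' together with a manifest recording the seed and a configuration hash;
#' re-running with an unchanged configuration leaves existing artifacts in
#' place. Outputs are deterministic given (config, seed).
#'
#' @param config An [analysis_config()].
#' @return A list of class `collider_analysis`: the inputs, strata, fitted
#'   `params`, weighted `cohort`, `iterations` (three `cox_result`s) and
#'   the `hr` summary tibble.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))

  if (config$mode == "synthetic") {
    sim <- config$simulation
    if (!is.null(config$seed)) sim$seed <- config$seed
    population <- simulate_population(sim)
    summary <- derive_external_summary(population)
    cohort <- restrict_to_hospitalised(population)
  } else {
    population <- NULL
    summary <- read_summary_csv(config$summary_path)
    cohort <- read_cohort_csv(config$cohort_path)
  }
  cohort <- ensure_died(cohort)

  if (config$model_form == "eq1") {
    summary <- dplyr::filter(summary, .data$wave == 1L)
    cohort <- dplyr::filter(cohort, .data$wave == 1L)
  }

  strata <- build_strata_from_marginals(
    summary, config$hospitalised_death_fraction
  )
  params <- fit_inclusion_model(strata, config$model_form)
  cohort <- derive_weights(params, cohort)
  iterations <- run_model_iterations(cohort)
  hr <- summarise_hr(iterations)

  result <- structure(
    list(
      config = config, population = population, summary = summary,
      strata = strata, params = params, cohort = cohort,
      iterations = iterations, hr = hr
    ),
    class = "collider_analysis"
  )
  if (!is.null(config$output_dir)) persist_analysis(result)
  result
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "output_dir")]
  rlang::hash(keep)
}

persist_analysis <- function(result) {
  config <- result$config
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("collideripw")),
    seed = config$seed,
    model_form = config$model_form,
    hospitalised_death_fraction = config$hospitalised_death_fraction,
    config_hash = config_hash(config),
    artifacts = c(
      "summary.csv", "strata.csv", "params.json",
      "weighted_cohort.csv", "hr_summary.csv"
    )
  )
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, manifest$config_hash) &&
        all(file.exists(file.path(dir, unlist(old$artifacts))))) {
      message("Artifacts up to date in ", dir, "; skipping write.")
      return(invisible(result))
    }
  }
  write_summary_csv(result$summary, file.path(dir, "summary.csv"))
  readr::write_csv(result$strata, file.path(dir, "strata.csv"))
  write_params_json(result$params, file.path(dir, "params.json"))
  write_cohort_csv(result$cohort, file.path(dir, "weighted_cohort.csv"))
  readr::write_csv(result$hr, file.path(dir, "hr_summary.csv"))
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(result)
}

#' @export
print.collider_analysis <- function(x, ...) {
  cat(
    "Collider-bias analysis (", x$config$model_form, ", ",
    x$config$mode, " mode): cohort n = ", nrow(x$cohort),
    ", deaths = ", sum(x$cohort$event_type == "death"), "\n\n",
    sep = ""
  )
  print(x$hr, n = Inf)
  invisible(x)
}

#' Misspecification sweep over a completed analysis
#'
#' For every scenario in the grid: shift the fitted coefficients, check the
#' implied probabilities of all modelled strata, apply the
#' invalid-probability policy, re-derive weights, and re-fit the weighted
#' (covariate-adjusted + IPW) Cox iteration. Invalid scenarios are handled
#' per policy and always recorded, never silently dropped.
#'
#' @param analysis A `collider_analysis` from [run_analysis()].
#' @param grid Scenario grid (defaults to [scenario_grid()] for the
#'   analysis' model form, honouring `scenario_grid_path`).
#' @param policy Invalid-probability policy, defaulting to the analysis
#'   config: `"skip"` (no fit; recorded), `"clip"` (probabilities capped
#'   at 1, i.e. weight 1), or `"shrink"` (shift scaled down to the largest
#'   valid multiple).
#' @return A list of class `sensitivity_result`: `results` (long tibble
#'   keyed by scenario and ethnicity), `validity` (per-stratum probability
#'   report for every scenario), `base_hr` (the unshifted weighted
#'   estimates), and metadata (`policy`).
#' @export
run_sensitivity <- function(analysis, grid = NULL, policy = NULL) {
  stopifnot(inherits(analysis, "collider_analysis"))
  config <- analysis$config
  policy <- policy %||% config$invalid_policy
  policy <- match.arg(policy, c("skip", "clip", "shrink"))
  grid <- grid %||% scenario_grid(config$model_form, config$scenario_grid_path)

  params <- analysis$params
  cohort <- analysis$cohort
  model_strata <- stratum_grid(config$model_form)
  covariates <- intersect(default_covariates(), names(cohort))
  base_fit <- analysis$iterations$weighted
  base_hr <- summarise_hr(list(weighted = base_fit))

  runs <- purrr::pmap(grid, function(scenario_id, target, level, delta, companion) {
    scenario <- list(
      scenario_id = scenario_id, target = target, delta = delta,
      companion = companion
    )
    shifted <- apply_scenario(params, scenario)
    report <- validate_probabilities(shifted, model_strata, baseline = params) %>%
      dplyr::mutate(scenario_id = scenario_id, .before = 1L)
    all_valid <- all(report$valid)
    action <- "fitted"
    scale_used <- 1
    if (!all_valid) {
      if (policy == "skip") {
        rlang::warn(paste0(
          "Scenario ", scenario_id, " pushes a stratum probability outside ",
          "(0, 1]; skipped under the 'skip' policy."
        ))
        return(list(
          rows = tibble::tibble(
            scenario_id = scenario_id, target = target, level = level,
            ethnicity = nonref_ethnicities(),
            hazard_ratio = NA_real_, ci_lower = NA_real_,
            ci_upper = NA_real_, p_value = NA_real_, log_hr = NA_real_,
            robust_se = NA_real_, action = "skipped", scale = NA_real_
          ),
          report = report
        ))
      } else if (policy == "shrink") {
        scale_used <- shrink_scale(params, scenario, model_strata)
        shifted <- apply_scenario(params, scale_scenario(scenario, scale_used))
        action <- "shrunk"
      } else {
        action <- "clipped"
      }
    }
    p <- predict_unclamped(shifted, cohort)
    p <- pmin(p, 1) # no-op except under the clip policy
    weights <- 1 / p
    refit <- fit_weighted_cox(
      dplyr::mutate(cohort, weight = weights),
      terms = c("ethnicity", covariates), use_weights = TRUE
    )
    rows <- summarise_hr(list(scenario = refit)) %>%
      dplyr::transmute(
        scenario_id = scenario_id, target = target, level = level,
        ethnicity = .data$ethnicity, hazard_ratio = .data$hazard_ratio,
        ci_lower = .data$ci_lower, ci_upper = .data$ci_upper,
        p_value = .data$p_value, log_hr = .data$log_hr,
        robust_se = .data$robust_se, action = action, scale = scale_used
      )
    list(rows = rows, report = report)
  })

  results <- purrr::map_dfr(runs, "rows")
  validity <- purrr::map_dfr(runs, "report")
  out <- structure(
    list(
      results = results, validity = validity, base_hr = base_hr,
      policy = policy, model_form = config$model_form
    ),
    class = "sensitivity_result"
  )
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(results, file.path(dir, "sensitivity_results.csv"))
    readr::write_csv(validity, file.path(dir, "sensitivity_validity.csv"))
    jsonlite::write_json(
      list(policy = policy, n_scenarios = nrow(grid)),
      file.path(dir, "sensitivity_meta.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

# Largest multiple s in (0, 1] of a scenario's shifts keeping every stratum
# probability at or below 1. The linear predictor is linear in s, so the
# bound per violating stratum is (log(1) - eta0) / shift.
shrink_scale <- function(params, scenario, strata) {
  scenario <- as_scenario(scenario)
  eta0 <- log(predict_unclamped(params, strata))
  eta1 <- log(predict_unclamped(apply_scenario(params, scenario), strata))
  shift <- eta1 - eta0
  eps <- 1e-9
  bad <- which(eta1 > 0)
  if (length(bad) == 0) {
    return(1)
  }
  bounds <- (0 - eps - eta0[bad]) / shift[bad]
  max(min(1, bounds), 0)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(
    "Misspecification sweep (", x$model_form, "), policy = ", x$policy,
    ": ", dplyr::n_distinct(x$results$scenario_id), " scenarios\n",
    sep = ""
  )
  print(dplyr::count(x$results, .data$target, .data$action), n = Inf)
  invisible(x)
}
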