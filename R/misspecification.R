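# Structured sensitivity analysis: additive log-scale shifts to individual
# selection-model coefficients at 50/100/200% of the evidence-suggested
# discrepancy, with companion shifts and probability-validity checking.

#' The misspecification scenario grid
#'
#' Expands the default (or a user-supplied) YAML grid into one scenario per
#' (coefficient, level): an additive shift `delta` on the log scale applied
#' to a single target coefficient, plus any companion shifts applied
#' simultaneously. The default grid shifts each non-reference coefficient
#' except those of the Unknown group at three nested levels (50%, 100%,
#' 200% of the externally suggested discrepancy); ethnicity-survivor
#' (`la`), wave main (`lg2`), ethnicity-wave (`lc`) and three-way (`ld`)
#' shifts carry a companion `-0.15` shift of the death main effect `lg1`
#' so died-stratum probabilities can rise without exceeding 1.
#'
#' @param model_form `"eq1"` (24 scenarios) or `"eq2"` (48: the `eq1`
#'   coefficients are part of the two-wave model and are shifted too).
#' @param path Optional path to a YAML grid with the same structure as the
#'   packaged default (`inst/extdata/misspecification_grid.yaml`).
#' @return Tibble with columns `scenario_id`, `target`, `level` (50, 100,
#'   200), `delta`, and `companion` (list column of named numeric shifts,
#'   possibly empty).
#' @export
#' @examples
#' scenario_grid("eq1")
scenario_grid <- function(model_form = c("eq1", "eq2"), path = NULL) {
  model_form <- match.arg(model_form)
  path <- path %||% system.file(
    "extdata", "misspecification_grid.yaml",
    package = "collideripw", mustWork = TRUE
  )
  spec <- yaml::read_yaml(path)
  companion_shift <- unlist(spec$companion) %||% c(lg1 = -0.15)
  entries <- spec$eq1
  if (model_form == "eq2") entries <- c(entries, spec$eq2)

  purrr::map_dfr(entries, function(entry) {
    levels <- as.integer(names(entry$deltas))
    tibble::tibble(
      target = entry$target,
      level = levels,
      delta = as.numeric(unlist(entry$deltas)),
      companion = if (isTRUE(entry$companion)) {
        rep(list(companion_shift), length(levels))
      } else {
        rep(list(stats::setNames(numeric(0), character(0))), length(levels))
      }
    )
  }) %>%
    dplyr::mutate(
      scenario_id = paste0(gsub("[^A-Za-z0-9]+", "", .data$target), "_", .data$level)
    ) %>%
    dplyr::select("scenario_id", "target", "level", "delta", "companion")
}

as_scenario <- function(scenario) {
  if (is.data.frame(scenario)) {
    if (nrow(scenario) != 1L) {
      cpw_config_error("`scenario` must be a single row of the scenario grid.")
    }
    scenario <- list(
      scenario_id = scenario$scenario_id %||% NA_character_,
      target = scenario$target,
      delta = scenario$delta,
      companion = scenario$companion[[1L]]
    )
  }
  scenario$companion <- scenario$companion %||% stats::setNames(numeric(0), character(0))
  scenario
}

#' Apply a misspecification scenario to fitted parameters
#'
#' Returns a new parameter set whose target coefficient is shifted by
#' `delta` on the log scale, with any companion shifts applied
#' simultaneously; the input object is untouched. Shifts compose
#' additively, so applying the negated deltas restores the original
#' coefficients exactly.
#'
#' @param params An `inclusion_model`.
#' @param scenario One row of [scenario_grid()], or a list with elements
#'   `target`, `delta` and optional named `companion` shifts.
#' @return The shifted `inclusion_model` (flagged as misspecified; fitted
#'   probabilities no longer equal observed risks).
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "inclusion_model"))
  scenario <- as_scenario(scenario)
  shifts <- c(
    stats::setNames(scenario$delta, scenario$target),
    scenario$companion
  )
  unknown <- setdiff(names(shifts), names(params$coefficients))
  if (length(unknown) > 0) {
    cpw_config_error(
      "Scenario shifts unknown coefficient(s): ",
      paste(unknown, collapse = ", "), " (model form ", params$model_form, ")."
    )
  }
  out <- params
  # a coefficient may appear as both target and companion; shifts accumulate
  for (nm in names(shifts)) {
    out$coefficients[[nm]] <- out$coefficients[[nm]] + shifts[[nm]]
  }
  out$misspecified <- TRUE
  out
}

scale_scenario <- function(scenario, s) {
  scenario <- as_scenario(scenario)
  scenario$delta <- scenario$delta * s
  scenario$companion <- scenario$companion * s
  scenario
}

#' Validity report for a (possibly shifted) parameter set
#'
#' Predicts the selection probability of every requested stratum under
#' `params`, flags probabilities outside (0, 1], and -- when a baseline
#' parameter set is supplied -- reports the direction of change relative to
#' the unshifted probabilities. Report-only: downstream policy decides what
#' to do with invalid scenarios.
#'
#' @param params The (shifted) `inclusion_model` to check.
#' @param strata Data frame of strata (`ethnicity`, `died`, `wave`);
#'   defaults to the model's own fitting strata.
#' @param baseline Optional unshifted `inclusion_model` for
#'   before-versus-after comparison.
#' @return Tibble with one row per stratum: `probability` (unclamped),
#'   `valid`, and when `baseline` is given `probability_before` and
#'   `direction` (sign of the change).
#' @export
validate_probabilities <- function(params, strata = NULL, baseline = NULL) {
  stopifnot(inherits(params, "inclusion_model"))
  strata <- strata %||% params$strata
  if (!"wave" %in% names(strata)) strata$wave <- 1L
  report <- tibble::tibble(
    ethnicity = as_ethnicity(strata$ethnicity),
    died = as.integer(strata$died),
    wave = as.integer(strata$wave)
  ) %>% dplyr::distinct()
  p_raw <- predict_unclamped(params, report)
  report$probability <- p_raw
  report$valid <- p_raw > 0 & p_raw <= 1
  if (!is.null(baseline)) {
    before <- predict_unclamped(baseline, report)
    report$probability_before <- before
    report$direction <- sign(p_raw - before)
  }
  report
}

predict_unclamped <- function(params, strata) {
  co <- params$coefficients
  eth <- as_ethnicity(strata$ethnicity)
  died <- as.integer(strata$died)
  wave2 <- as.integer(strata$wave == 2L)
  grab <- function(prefix) {
    v <- rep(0, length(eth))
    for (e in nonref_ethnicities()) {
      nm <- coef_name(prefix, e)
      if (nm %in% names(co)) v[eth == e] <- co[[nm]]
    }
    v
  }
  eta <- co[["lg0"]] + died * co[["lg1"]] + grab("la") + died * grab("lb")
  if (params$model_form == "eq2") {
    eta <- eta + wave2 * co[["lg2"]] + died * wave2 * co[["lg3"]] +
      wave2 * grab("lc") + died * wave2 * grab("ld")
  }
  exp(eta)
}
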