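# Synthetic source population with the collider structure: ethnicity raises
# the probability of hospitalisation among survivors, death strongly raises
# it, and ethnicity modifies the risk of death. Restricting to hospitalised
# admissions then induces collider bias in the ethnicity-death association.

#' Configuration for the synthetic population generator
#'
#' Defines a source population in which both the exposure (ethnic group) and
#' the outcome (death) influence selection (hospitalisation), the causal
#' structure under which restriction to a hospitalised cohort induces
#' collider bias. Defaults place survivor hospitalisation risks in the
#' 0.001--0.003 range and the probability of hospitalisation given death at
#' 0.90, the magnitudes of the external evidence the selection model is
#' normally fitted to.
#'
#' Death status is drawn first; hospitalisation is then drawn conditional on
#' (ethnicity, wave, died). Event times are exponential with separate rates
#' for death and discharge. With `rate_death == rate_discharge` (the
#' default) the full-population cause-specific hazard of death is constant
#' within each stratum and the death hazard ratio between two ethnic groups
#' equals their death-risk ratio exactly, so the generative log hazard
#' ratios are known analytically.
#'
#' @param population_size Number of simulated persons.
#' @param ethnicity_proportions Named probabilities per ethnic group
#'   (must cover [ethnicity_levels()] and sum to 1).
#' @param wave_proportions Probabilities of admission in waves 1 and 2
#'   (length 2, sums to 1).
#' @param baseline_death_risk Probability of death for the reference group
#'   (White) in wave 1.
#' @param death_risk_multipliers Named per-ethnicity multiplicative effects
#'   on the death risk; the "true" exposure--outcome effect.
#' @param baseline_hosp_risk_survivor Probability of hospitalisation for a
#'   White wave-1 survivor.
#' @param hosp_risk_multipliers_survivor Named per-ethnicity multiplicative
#'   effects on survivor hospitalisation risk (the exposure-to-selection
#'   arrow of the collider).
#' @param hosp_prob_death Probability of hospitalisation given death; a
#'   scalar (applied to every ethnicity) or a named per-ethnicity vector.
#'   Wave-independent, matching the usual "fraction of deaths occurring in
#'   hospital" assumption.
#' @param wave2_hosp_multiplier Multiplier on survivor hospitalisation risk
#'   in wave 2.
#' @param wave2_death_multiplier Multiplier on death risk in wave 2.
#' @param covariate_model Output of [covariate_model()]: marginal
#'   distributions for the nine baseline covariates, optionally shifted by
#'   ethnicity.
#' @param survival_time_model List with `rate_death`, `rate_discharge`
#'   (events/day) and `censor_horizon` (days; `Inf` disables administrative
#'   censoring).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(population_size = 5000, seed = 1)
#' pop <- simulate_population(cfg)
#' dplyr::count(pop, ethnicity, died)
simulation_config <- function(population_size = 200000,
                              ethnicity_proportions = c(
                                "White" = 0.55, "Black" = 0.14, "Asian" = 0.13,
                                "Mixed/Other" = 0.10, "Unknown" = 0.08
                              ),
                              wave_proportions = c(0.5, 0.5),
                              baseline_death_risk = 0.01,
                              death_risk_multipliers = c(
                                "White" = 1, "Black" = 1.1, "Asian" = 1.2,
                                "Mixed/Other" = 1.0, "Unknown" = 0.9
                              ),
                              baseline_hosp_risk_survivor = 0.00126,
                              hosp_risk_multipliers_survivor = c(
                                "White" = 1,
                                "Black" = 0.00238 / 0.00126,
                                "Asian" = 0.00197 / 0.00126,
                                "Mixed/Other" = 0.00155 / 0.00126,
                                "Unknown" = 0.00101 / 0.00126
                              ),
                              hosp_prob_death = 0.90,
                              wave2_hosp_multiplier = 0.00068 / 0.00126,
                              wave2_death_multiplier = 0.5,
                              covariate_model = NULL,
                              survival_time_model = list(
                                family = "exponential",
                                rate_death = 0.1,
                                rate_discharge = 0.1,
                                censor_horizon = Inf
                              ),
                              seed = NULL) {
  eths <- ethnicity_levels()
  ethnicity_proportions <- check_named_per_ethnicity(
    ethnicity_proportions, "ethnicity_proportions"
  )
  death_risk_multipliers <- check_named_per_ethnicity(
    death_risk_multipliers, "death_risk_multipliers"
  )
  hosp_risk_multipliers_survivor <- check_named_per_ethnicity(
    hosp_risk_multipliers_survivor, "hosp_risk_multipliers_survivor"
  )
  if (length(hosp_prob_death) == 1L && is.null(names(hosp_prob_death))) {
    hosp_prob_death <- stats::setNames(rep(hosp_prob_death, length(eths)), eths)
  }
  hosp_prob_death <- check_named_per_ethnicity(hosp_prob_death, "hosp_prob_death")

  if (length(population_size) != 1L || population_size < 1 ||
      population_size != round(population_size)) {
    cpw_config_error("`population_size` must be a positive integer.")
  }
  if (abs(sum(ethnicity_proportions) - 1) > 1e-9) {
    cpw_config_error("`ethnicity_proportions` must sum to 1 (within 1e-9).")
  }
  if (length(wave_proportions) != 2L || abs(sum(wave_proportions) - 1) > 1e-9 ||
      any(wave_proportions < 0)) {
    cpw_config_error("`wave_proportions` must be two non-negative values summing to 1.")
  }
  if (baseline_death_risk < 0 || baseline_death_risk > 1) {
    cpw_config_error("`baseline_death_risk` must be a probability in [0, 1].")
  }

  cfg <- structure(
    list(
      population_size = as.integer(population_size),
      ethnicity_proportions = ethnicity_proportions,
      wave_proportions = wave_proportions,
      baseline_death_risk = baseline_death_risk,
      death_risk_multipliers = death_risk_multipliers,
      baseline_hosp_risk_survivor = baseline_hosp_risk_survivor,
      hosp_risk_multipliers_survivor = hosp_risk_multipliers_survivor,
      hosp_prob_death = hosp_prob_death,
      wave2_hosp_multiplier = wave2_hosp_multiplier,
      wave2_death_multiplier = wave2_death_multiplier,
      covariate_model = covariate_model %||% covariate_model(),
      survival_time_model = survival_time_model,
      seed = seed
    ),
    class = "simulation_config"
  )
  # every stratum probability must be a valid probability after multipliers
  check_stratum_probabilities(cfg)
  cfg
}

check_named_per_ethnicity <- function(x, what) {
  eths <- ethnicity_levels()
  if (is.null(names(x)) || !setequal(names(x), eths)) {
    cpw_config_error(
      "`", what, "` must be named with exactly the categories: ",
      paste(eths, collapse = ", "), "."
    )
  }
  x[eths]
}

# Per-stratum generative probabilities implied by a configuration.
stratum_probabilities <- function(config) {
  stratum_grid("eq2") %>%
    dplyr::mutate(
      p_death = config$baseline_death_risk *
        unname(config$death_risk_multipliers[as.character(.data$ethnicity)]) *
        ifelse(.data$wave == 2L, config$wave2_death_multiplier, 1),
      p_hosp = ifelse(
        .data$died == 1L,
        unname(config$hosp_prob_death[as.character(.data$ethnicity)]),
        config$baseline_hosp_risk_survivor *
          unname(config$hosp_risk_multipliers_survivor[as.character(.data$ethnicity)]) *
          ifelse(.data$wave == 2L, config$wave2_hosp_multiplier, 1)
      )
    )
}

check_stratum_probabilities <- function(config) {
  probs <- stratum_probabilities(config)
  bad <- probs %>%
    tidyr::pivot_longer(c("p_death", "p_hosp"),
      names_to = "which", values_to = "p"
    ) %>%
    dplyr::filter(.data$p < 0 | .data$p > 1)
  if (nrow(bad) > 0) {
    first <- bad[1L, ]
    cpw_config_error(
      "Stratum probability outside [0, 1] after applying multipliers: ",
      first$which, " = ", format(first$p), " in stratum (",
      first$ethnicity, ", died = ", first$died, ", wave = ", first$wave, ")."
    )
  }
  invisible(config)
}

#' Baseline covariate model for the simulator
#'
#' Marginal distributions for the nine baseline covariates attached to each
#' simulated person: age (normal), sex and six comorbidity/DNR indicators
#' (Bernoulli) and IMD quintile (categorical 1--5). By default covariates
#' are independent of the ethnicity-to-death path, so the generative hazard
#' ratios of the default scenario are unchanged by covariate adjustment;
#' per-ethnicity shifts can be supplied to break that independence.
#'
#' @param age_mean,age_sd Mean and SD of age in years; `age_mean` may be a
#'   named per-ethnicity vector.
#' @param prevalence Named list of Bernoulli prevalences for `sex`, `dnr`,
#'   `cardiovascular`, `copd`, `diabetes`, `liver`, `kidney`; each entry a
#'   scalar or a named per-ethnicity vector.
#' @param imd_probs Probabilities of IMD quintiles 1--5 (sum to 1).
#' @return A list of class `covariate_model`.
#' @export
covariate_model <- function(age_mean = 60, age_sd = 15,
                            prevalence = list(
                              sex = 0.5, dnr = 0.2, cardiovascular = 0.25,
                              copd = 0.1, diabetes = 0.2, liver = 0.03,
                              kidney = 0.1
                            ),
                            imd_probs = rep(0.2, 5)) {
  needed <- c("sex", "dnr", "cardiovascular", "copd", "diabetes", "liver", "kidney")
  missing <- setdiff(needed, names(prevalence))
  if (length(missing) > 0) {
    cpw_config_error(
      "`prevalence` must include: ", paste(missing, collapse = ", "), "."
    )
  }
  if (length(imd_probs) != 5L || abs(sum(imd_probs) - 1) > 1e-9) {
    cpw_config_error("`imd_probs` must be 5 probabilities summing to 1.")
  }
  structure(
    list(age_mean = age_mean, age_sd = age_sd, prevalence = prevalence,
         imd_probs = imd_probs),
    class = "covariate_model"
  )
}

per_ethnicity_value <- function(x, ethnicity) {
  if (length(x) == 1L && is.null(names(x))) {
    rep(x, length(ethnicity))
  } else {
    unname(x[as.character(ethnicity)])
  }
}

#' Simulate a source population with the collider structure
#'
#' Draws a population in which ethnicity affects both death risk and
#' (among survivors) hospitalisation risk, and death strongly raises the
#' probability of hospitalisation. Death is drawn first, then
#' hospitalisation conditional on (ethnicity, wave, died), then an
#' exponential event time (death or discharge) with administrative
#' censoring at the configured horizon.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per person: `id`, `ethnicity`, `wave`,
#'   `died`, `hospitalised`, `time_to_event` (days), `event_type`
#'   (`"death"`, `"discharge"` or `"censored"`) and the nine baseline
#'   covariates.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  check_stratum_probabilities(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$population_size
  eths <- ethnicity_levels()
  ethnicity <- factor(
    sample(eths, n, replace = TRUE, prob = config$ethnicity_proportions),
    levels = eths
  )
  wave <- sample(c(1L, 2L), n, replace = TRUE, prob = config$wave_proportions)

  p_death <- config$baseline_death_risk *
    unname(config$death_risk_multipliers[as.character(ethnicity)]) *
    ifelse(wave == 2L, config$wave2_death_multiplier, 1)
  died <- as.integer(stats::runif(n) < p_death)

  p_hosp <- ifelse(
    died == 1L,
    unname(config$hosp_prob_death[as.character(ethnicity)]),
    config$baseline_hosp_risk_survivor *
      unname(config$hosp_risk_multipliers_survivor[as.character(ethnicity)]) *
      ifelse(wave == 2L, config$wave2_hosp_multiplier, 1)
  )
  hospitalised <- as.integer(stats::runif(n) < p_hosp)

  stm <- config$survival_time_model
  time_raw <- ifelse(
    died == 1L,
    stats::rexp(n, rate = stm$rate_death),
    stats::rexp(n, rate = stm$rate_discharge)
  )
  horizon <- stm$censor_horizon %||% Inf
  censored <- time_raw > horizon
  time_to_event <- pmin(time_raw, horizon)
  event_type <- dplyr::case_when(
    censored ~ "censored",
    died == 1L ~ "death",
    TRUE ~ "discharge"
  )

  cm <- config$covariate_model
  pop <- tibble::tibble(
    id = seq_len(n),
    ethnicity = ethnicity,
    wave = wave,
    died = died,
    hospitalised = hospitalised,
    time_to_event = time_to_event,
    event_type = event_type,
    age = stats::rnorm(n,
      mean = per_ethnicity_value(cm$age_mean, ethnicity), sd = cm$age_sd
    ),
    imd_quintile = sample(1:5, n, replace = TRUE, prob = cm$imd_probs)
  )
  for (cov in names(cm$prevalence)) {
    p <- per_ethnicity_value(cm$prevalence[[cov]], ethnicity)
    pop[[cov]] <- as.integer(stats::runif(n) < p)
  }
  pop
}

#' Tally the marginal external-style summary from a population
#'
#' Collapses a simulated population to the marginal per-(ethnicity, wave)
#' counts an external published analysis would report: population
#' denominator, number hospitalised, number died. Deliberately marginal --
#' no hospitalisation-by-survival cross-tabulation -- mirroring the
#' summary-level sources available in practice.
#'
#' @param population Tibble from [simulate_population()].
#' @return Tibble with columns `ethnicity`, `wave`, `n_total`,
#'   `n_hospitalised`, `n_died` (zero rows filled in for empty strata).
#' @export
derive_external_summary <- function(population) {
  if (nrow(population) == 0) {
    cpw_config_error("`population` must be non-empty.")
  }
  waves <- sort(unique(population$wave))
  population %>%
    dplyr::mutate(ethnicity = as_ethnicity(.data$ethnicity)) %>%
    dplyr::group_by(.data$ethnicity, .data$wave) %>%
    dplyr::summarise(
      n_total = dplyr::n(),
      n_hospitalised = sum(.data$hospitalised),
      n_died = sum(.data$died),
      .groups = "drop"
    ) %>%
    tidyr::complete(
      ethnicity = factor(ethnicity_levels(), levels = ethnicity_levels()),
      wave = waves,
      fill = list(n_total = 0L, n_hospitalised = 0L, n_died = 0L)
    ) %>%
    dplyr::arrange(.data$ethnicity, .data$wave)
}

#' Restrict a population to the hospitalised cohort
#'
#' Keeps exactly the persons with `hospitalised == 1`. This is the
#' conditioning-on-selection step that induces collider bias: within the
#' restricted cohort, ethnicity and death become spuriously associated even
#' when covariates are balanced.
#'
#' @param population Tibble from [simulate_population()].
#' @return The hospitalised admissions as a tibble (a cohort), with
#'   `weight = 1` attached.
#' @export
restrict_to_hospitalised <- function(population) {
  cohort <- dplyr::filter(population, .data$hospitalised == 1L)
  if (nrow(cohort) == 0) {
    rlang::warn("Restriction produced an empty cohort: no hospitalised persons.")
  }
  dplyr::mutate(cohort, weight = 1)
}
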