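# Shared fixtures: small generative scenarios and strata tables built in code.

# Roomy stratum risks so every cell count is comfortably positive at modest n;
# used for contract tests that do not depend on the thin-risk study conditions.
roomy_sim_config <- function(n = 20000, seed = 42, waves = c(0.5, 0.5),
                             baseline_death_risk = 0.10,
                             baseline_hosp_risk_survivor = 0.05,
                             hosp_prob_death = 0.90, ...) {
  simulation_config(
    population_size = n,
    wave_proportions = waves,
    baseline_death_risk = baseline_death_risk,
    baseline_hosp_risk_survivor = baseline_hosp_risk_survivor,
    hosp_prob_death = hosp_prob_death,
    wave2_death_multiplier = 0.8,
    wave2_hosp_multiplier = 0.8,
    seed = seed,
    ...
  )
}

# The study-condition scenario: survivor hospitalisation risks around
# 0.001-0.003, probability of hospitalisation given death 0.90, true
# Black-vs-White death hazard ratio 1.1, single wave.
collider_sim_config <- function(n = 200000, seed = 1234) {
  simulation_config(
    population_size = n,
    wave_proportions = c(1, 0),
    seed = seed
  )
}

# A full strata table with arbitrary (valid) risks per cell.
random_strata <- function(model_form = "eq1", n_at_risk = 10000,
                          rmin = 0.01, rmax = 0.99) {
  grid <- stratum_grid(model_form)
  grid$n_at_risk <- n_at_risk
  grid$risk <- stats::runif(nrow(grid), rmin, rmax)
  grid$n_hospitalised <- grid$risk * grid$n_at_risk
  grid
}

# Strata table with the same two risks (survived / died) in every ethnic
# group and wave.
uniform_strata <- function(risk_survived, risk_died, model_form = "eq1",
                           n_at_risk = 1000) {
  grid <- stratum_grid(model_form)
  grid$n_at_risk <- n_at_risk
  grid$risk <- ifelse(grid$died == 1L, risk_died, risk_survived)
  grid$n_hospitalised <- grid$risk * grid$n_at_risk
  grid
}

# Hand-settable parameter object mirroring fit_inclusion_model() output.
manual_params <- function(exp_coefs, model_form = "eq1") {
  coefs <- log(exp_coefs)
  structure(
    list(
      model_form = model_form,
      coefficients = coefs,
      se_log = rep(NA_real_, length(coefs)),
      se_exp = rep(NA_real_, length(coefs)),
      strata = NULL,
      misspecified = FALSE
    ),
    class = "inclusion_model"
  )
}

# Exponentiated coefficients printed for the single-wave selection model.
table1_exp_coefs <- function() {
  c(
    lg0 = 0.0012, lg1 = 823.70,
    "la_Black" = 1.9190, "la_Asian" = 1.5922,
    "la_Mixed/Other" = 1.2581, "la_Unknown" = 0.7944,
    "lb_Black" = 0.5211, "lb_Asian" = 0.6280,
    "lb_Mixed/Other" = 0.7949, "lb_Unknown" = 1.2587
  )
}

# Fixed 6-record cohort with distinct event times for partial-likelihood
# oracle checks; `group` is a Black-vs-White contrast.
six_record_cohort <- function() {
  tibble::tibble(
    id = 1:6,
    ethnicity = c("Black", "White", "Black", "White", "Black", "White"),
    wave = 1L,
    time_to_event = c(3.1, 4.7, 6.2, 8.9, 11.4, 13.8),
    event_type = c("death", "discharge", "death", "death", "discharge", "death"),
    died = c(1L, 0L, 1L, 1L, 0L, 1L),
    weight = 1
  )
}

# Independent oracle: cause-specific Cox log partial likelihood for a single
# binary covariate, no ties, evaluated directly from its definition.
cox_loglik_1cov <- function(beta, time, status, x, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(status == 1L)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (x[i] * beta -
      log(sum(w[risk] * exp(x[risk] * beta))))
  }
  ll
}
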