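# Saturated log-link selection model: closed-form fit, oracle equivalence,
# the iterative route, prediction and weight derivation.

ratio_oracle <- function(strata, model_form) {
  # independent oracle: exponentiated coefficients as direct ratios/products
  # of observed cell risks
  r <- function(e, d, w) {
    strata$risk[strata$ethnicity == e & strata$died == d & strata$wave == w]
  }
  out <- c(lg0 = r("White", 0, 1), lg1 = r("White", 1, 1) / r("White", 0, 1))
  for (e in setdiff(ethnicity_levels(), "White")) {
    out[paste0("la_", e)] <- r(e, 0, 1) / r("White", 0, 1)
    out[paste0("lb_", e)] <- (r(e, 1, 1) / r(e, 0, 1)) /
      (r("White", 1, 1) / r("White", 0, 1))
  }
  if (model_form == "eq2") {
    out["lg2"] <- r("White", 0, 2) / r("White", 0, 1)
    out["lg3"] <- (r("White", 1, 2) / r("White", 0, 2)) /
      (r("White", 1, 1) / r("White", 0, 1))
    for (e in setdiff(ethnicity_levels(), "White")) {
      out[paste0("lc_", e)] <- (r(e, 0, 2) / r(e, 0, 1)) /
        (r("White", 0, 2) / r("White", 0, 1))
      out[paste0("ld_", e)] <- (r(e, 1, 2) / r(e, 0, 2) / (r(e, 1, 1) / r(e, 0, 1))) /
        (r("White", 1, 2) / r("White", 0, 2) / (r("White", 1, 1) / r("White", 0, 1)))
    }
  }
  out
}

test_that("a two-risk table gives intercept and death effect only", {
  st <- uniform_strata(risk_survived = 0.2, risk_died = 0.8)
  fit <- fit_inclusion_model(st, "eq1")
  co <- exp(fit$coefficients)
  expect_equal(unname(co["lg0"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(co["lg1"]), 4.0, tolerance = 1e-12)
  lambdas <- co[grepl("^l[ab]_", names(co))]
  expect_equal(unname(lambdas), rep(1, 8), tolerance = 1e-12)
})

test_that("saturated fit reproduces every cell risk and every risk-ratio coefficient", {
  set.seed(21)
  for (form in c("eq1", "eq2")) {
    for (i in 1:25) {
      st <- random_strata(form)
      fit <- fit_inclusion_model(st, form)
      expect_equal(
        predict_probability(fit, st), st$risk,
        tolerance = 1e-13
      )
      oracle <- ratio_oracle(st, form)
      expect_equal(
        exp(fit$coefficients)[names(oracle)], oracle,
        tolerance = 1e-12
      )
    }
  }
})

test_that("the wave main effect equals the White survivor risk ratio across waves", {
  st <- uniform_strata(0.00126, 0.90, model_form = "eq2", n_at_risk = 1e6)
  st$risk[st$ethnicity == "White" & st$died == 0 & st$wave == 2] <- 0.00068
  st$n_hospitalised <- st$risk * st$n_at_risk
  fit <- fit_inclusion_model(st, "eq2")
  expect_equal(
    unname(exp(fit$coefficients["lg2"])), 0.00068 / 0.00126,
    tolerance = 1e-12
  )
  # agrees with the published two-wave fit within input rounding
  expect_lt(abs(exp(fit$coefficients[["lg2"]]) - 0.5405), 0.002)
})

test_that("the iterative log-binomial route matches the closed form", {
  set.seed(22)
  for (form in c("eq1", "eq2")) {
    st <- random_strata(form, rmin = 0.002, rmax = 0.9)
    closed <- fit_inclusion_model(st, form)
    iterative <- fit_inclusion_glm(st, form)
    expect_equal(
      iterative$coefficients[names(closed$coefficients)],
      closed$coefficients,
      tolerance = 1e-8
    )
  }
})

test_that("standard errors follow the observed-information formula", {
  st <- uniform_strata(0.2, 0.8, n_at_risk = 500)
  fit <- fit_inclusion_model(st, "eq1")
  v <- function(p, n) (1 - p) / (n * p)
  expect_equal(unname(fit$se_log["lg0"]), sqrt(v(0.2, 500)), tolerance = 1e-12)
  expect_equal(
    unname(fit$se_log["lg1"]), sqrt(v(0.2, 500) + v(0.8, 500)),
    tolerance = 1e-12
  )
  expect_equal(fit$se_exp, exp(fit$coefficients) * fit$se_log,
    tolerance = 1e-12
  )
})

test_that("prediction composes the linear predictor from printed-style parameters", {
  params <- manual_params(table1_exp_coefs())
  # reference survivor: intercept only
  p_ref <- predict_probability(
    params, tibble::tibble(ethnicity = "White", died = 0, wave = 1)
  )
  expect_equal(p_ref, 0.0012, tolerance = 1e-12)
  # non-reference died stratum: product of the four applicable parameters
  p_black_died <- predict_probability(
    params, tibble::tibble(ethnicity = "Black", died = 1, wave = 1)
  )
  expect_equal(p_black_died, 0.0012 * 823.70 * 1.9190 * 0.5211,
    tolerance = 1e-12
  )
  # rounded published parameters multiply out near 0.99, not the design 0.90
  expect_gt(p_black_died, 0.98)
})

test_that("null coefficients predict probability one for every stratum", {
  st <- uniform_strata(1, 1)
  fit <- fit_inclusion_model(st, "eq1")
  expect_equal(unname(fit$coefficients), rep(0, 10), tolerance = 1e-12)
  p <- predict_probability(fit, stratum_grid("eq1"))
  expect_equal(p, rep(1, 10), tolerance = 1e-12)
  w <- derive_weights(fit, dplyr::mutate(stratum_grid("eq1"), id = 1:10))
  expect_equal(w$weight, rep(1, 10), tolerance = 1e-12)
})

test_that("weights are reciprocal probabilities and constant within stratum", {
  params <- manual_params(table1_exp_coefs())
  cohort <- tibble::tibble(
    ethnicity = c("White", "White", "Black"),
    died = c(0L, 0L, 0L), wave = 1L
  )
  w <- derive_weights(params, cohort)
  expect_equal(w$weight[1], 1 / 0.0012, tolerance = 1e-12)
  expect_equal(w$weight[1], w$weight[2])
  expect_equal(w$weight[3], 1 / (0.0012 * 1.9190), tolerance = 1e-12)
})

test_that("degenerate and inconsistent strata are rejected with named cells", {
  st <- uniform_strata(0.2, 0.8)
  st$n_hospitalised[st$ethnicity == "Asian" & st$died == 1] <- 0
  expect_error(fit_inclusion_model(st, "eq1"), "Asian",
    class = "collideripw_model_error"
  )
  st2 <- uniform_strata(0.2, 0.8)
  st2$n_hospitalised[2] <- st2$n_at_risk[2] * 1.2
  expect_error(fit_inclusion_model(st2, "eq1"),
    class = "collideripw_evidence_error"
  )
  fit <- fit_inclusion_model(uniform_strata(0.2, 0.8), "eq1")
  expect_error(
    predict_probability(fit, tibble::tibble(ethnicity = "White", died = 0, wave = 2)),
    class = "collideripw_config_error"
  )
  expect_error(
    derive_weights(fit, tibble::tibble(ethnicity = "Martian", died = 0, wave = 1)),
    class = "collideripw_config_error"
  )
})

test_that("increasing a coefficient increases exactly the strata containing it", {
  set.seed(23)
  st <- random_strata("eq2", rmin = 0.05, rmax = 0.5)
  fit <- fit_inclusion_model(st, "eq2")
  grid <- stratum_grid("eq2")
  base <- predict_probability(fit, grid, check = FALSE)
  for (nm in c("lg1", "la_Black", "lb_Asian", "lc_Mixed/Other", "ld_Unknown")) {
    bumped <- fit
    bumped$coefficients[[nm]] <- bumped$coefficients[[nm]] + 0.05
    p <- predict_probability(bumped, grid, check = FALSE)
    affected <- switch(substr(nm, 1, 2),
      lg = grid$died == 1L,
      la = grid$ethnicity == sub("^la_", "", nm),
      lb = grid$ethnicity == sub("^lb_", "", nm) & grid$died == 1L,
      lc = grid$ethnicity == sub("^lc_", "", nm) & grid$wave == 2L,
      ld = grid$ethnicity == sub("^ld_", "", nm) & grid$died == 1L & grid$wave == 2L
    )
    expect_true(all(p[affected] > base[affected]))
    expect_equal(p[!affected], base[!affected], tolerance = 1e-15)
  }
})

test_that("stratum weight-sums reconstruct the full population (pseudo-population)", {
  cfg <- roomy_sim_config(n = 40000, seed = 24)
  pop <- simulate_population(cfg)
  cohort <- restrict_to_hospitalised(pop)

  # exact route: strata from the population's own cross-tabulation
  truth <- pop %>%
    dplyr::group_by(ethnicity, wave, died) %>%
    dplyr::summarise(
      n_at_risk = dplyr::n(), n_hospitalised = sum(hospitalised),
      .groups = "drop"
    )
  fit <- fit_inclusion_model(truth, "eq2")
  weighted <- derive_weights(fit, cohort) %>%
    dplyr::group_by(ethnicity, wave, died) %>%
    dplyr::summarise(w = sum(weight), .groups = "drop") %>%
    dplyr::left_join(truth, by = c("ethnicity", "wave", "died"))
  expect_equal(weighted$w, weighted$n_at_risk, tolerance = 1e-9)

  # marginal route with the generative 0.90 assumption: close, not exact
  st <- build_strata_from_marginals(derive_external_summary(pop), 0.9)
  fit2 <- fit_inclusion_model(st, "eq2")
  weighted2 <- derive_weights(fit2, cohort) %>%
    dplyr::group_by(ethnicity, wave, died) %>%
    dplyr::summarise(w = sum(weight), .groups = "drop") %>%
    dplyr::left_join(truth, by = c("ethnicity", "wave", "died"))
  expect_lt(max(abs(weighted2$w / weighted2$n_at_risk - 1)), 0.25)
})
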