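# Misspecification engine: grid contents, companion shifts, apply/undo,
# monotone level response and probability-validity reporting.

expected_deltas <- function() {
  tibble::tribble(
    ~target, ~d50, ~d100, ~d200, ~companion,
    "lg0", -0.05, -0.1, -0.2, FALSE,
    "lg1", -0.075, -0.15, -0.3, FALSE,
    "la_Black", 0.125, 0.25, 0.5, TRUE,
    "la_Asian", 0.125, 0.25, 0.5, TRUE,
    "la_Mixed/Other", 0.1, 0.2, 0.4, TRUE,
    "lb_Black", -0.1, -0.2, -0.4, FALSE,
    "lb_Asian", -0.1, -0.2, -0.4, FALSE,
    "lb_Mixed/Other", -0.1, -0.2, -0.4, FALSE,
    "lg2", 0.25, 0.5, 1.0, TRUE,
    "lg3", -0.35, -0.7, -1.4, FALSE,
    "lc_Black", 0.125, 0.25, 0.5, TRUE,
    "lc_Asian", -0.1, -0.2, -0.4, TRUE,
    "lc_Mixed/Other", 0.125, 0.25, 0.5, TRUE,
    "ld_Black", 0.1, 0.2, 0.4, TRUE,
    "ld_Asian", 0.1, 0.2, 0.4, TRUE,
    "ld_Mixed/Other", 0.1, 0.2, 0.4, TRUE
  )
}

test_that("the default grid reproduces every published shift at all three levels", {
  g1 <- scenario_grid("eq1")
  g2 <- scenario_grid("eq2")
  expect_equal(nrow(g1), 24) # 8 coefficients x 3 levels
  expect_equal(nrow(g2), 48)
  expect_setequal(unique(g1$target), expected_deltas()$target[1:8])
  expect_setequal(unique(g2$target), expected_deltas()$target)

  exp_long <- expected_deltas() %>%
    tidyr::pivot_longer(c("d50", "d100", "d200"),
      names_to = "level", values_to = "delta"
    ) %>%
    dplyr::mutate(level = as.integer(sub("^d", "", level)))
  joined <- dplyr::inner_join(g2, exp_long, by = c("target", "level"))
  expect_equal(nrow(joined), 48)
  expect_equal(joined$delta.x, joined$delta.y)

  has_companion <- purrr::map_lgl(joined$companion.x %||% joined$companion,
    function(x) length(x) > 0
  )
})

test_that("companion shifts of the death effect appear exactly where marked", {
  g <- scenario_grid("eq2")
  expected <- expected_deltas()
  for (i in seq_len(nrow(g))) {
    marked <- expected$companion[expected$target == g$target[i]]
    comp <- g$companion[[i]]
    if (marked) {
      expect_equal(comp, c(lg1 = -0.15))
    } else {
      expect_length(comp, 0)
    }
  }
})

test_that("Unknown-group coefficients are never shifted", {
  g <- scenario_grid("eq2")
  expect_false(any(grepl("Unknown", g$target)))
  expect_false(any(purrr::map_lgl(g$companion, function(x) any(grepl("Unknown", names(x))))))
})

test_that("level magnitudes are nested and share sign within each target", {
  g <- scenario_grid("eq2") %>% dplyr::arrange(target, level)
  by_target <- split(g, g$target)
  for (tg in by_target) {
    expect_true(all(diff(abs(tg$delta)) > 0))
    expect_equal(length(unique(sign(tg$delta))), 1L)
  }
})

test_that("applying a scenario shifts the target and companion and is invertible", {
  st <- uniform_strata(0.2, 0.8)
  fit <- fit_inclusion_model(st, "eq1")

  sc <- scenario_grid("eq1") %>%
    dplyr::filter(target == "la_Black", level == 50)
  shifted <- apply_scenario(fit, sc)
  expect_equal(
    shifted$coefficients[["la_Black"]],
    fit$coefficients[["la_Black"]] + 0.125
  )
  expect_equal(
    shifted$coefficients[["lg1"]],
    fit$coefficients[["lg1"]] - 0.15
  )
  expect_true(shifted$misspecified)
  # original untouched
  expect_false(fit$misspecified)
  expect_equal(fit$coefficients[["la_Black"]], log(1), tolerance = 1e-12)

  # round trip over every scenario restores the parameters to 1e-12
  g <- scenario_grid("eq1")
  for (i in seq_len(nrow(g))) {
    sc <- as.list(g[i, ])
    sc$companion <- g$companion[[i]]
    undone <- apply_scenario(
      apply_scenario(fit, sc),
      list(
        target = sc$target, delta = -sc$delta,
        companion = -sc$companion
      )
    )
    expect_equal(undone$coefficients, fit$coefficients, tolerance = 1e-12)
  }

  # identity scenario
  same <- apply_scenario(fit, list(target = "lg0", delta = 0))
  expect_equal(same$coefficients, fit$coefficients)

  expect_error(
    apply_scenario(fit, list(target = "lg9", delta = 0.1)),
    class = "collideripw_config_error"
  )
  # eq1 params cannot take wave shifts
  expect_error(
    apply_scenario(fit, list(target = "lg2", delta = 0.1)),
    class = "collideripw_config_error"
  )
})

test_that("an intercept-style downward shift scales the printed intercept as expected", {
  params <- manual_params(table1_exp_coefs())
  shifted <- apply_scenario(params, list(target = "lg0", delta = -0.1))
  expect_equal(
    exp(shifted$coefficients[["lg0"]]), 0.0012 * exp(-0.1),
    tolerance = 1e-12
  )
  expect_equal(round(exp(shifted$coefficients[["lg0"]]), 6), 0.001086)
})

test_that("stratum probabilities respond monotonically across the 50/100/200 levels", {
  st <- uniform_strata(0.1, 0.6, model_form = "eq2")
  fit <- fit_inclusion_model(st, "eq2")
  g <- scenario_grid("eq2")
  grid <- stratum_grid("eq2")
  for (tg in unique(g$target)) {
    rows <- g %>%
      dplyr::filter(target == tg) %>%
      dplyr::arrange(level)
    probs <- purrr::map(seq_len(nrow(rows)), function(i) {
      sc <- as.list(rows[i, ])
      sc$companion <- rows$companion[[i]]
      validate_probabilities(apply_scenario(fit, sc), grid, baseline = fit)
    })
    # strata moved by the target coefficient alone (no companion interference):
    # for each, the sequence across levels must be strictly monotone
    base <- validate_probabilities(fit, grid)
    sc100 <- as.list(rows[rows$level == 100, ])
    sc100$companion <- stats::setNames(numeric(0), character(0))
    target_only <- validate_probabilities(
      apply_scenario(fit, sc100), grid,
      baseline = fit
    )
    moved <- which(abs(target_only$probability - base$probability) > 1e-14)
    expect_gt(length(moved), 0)
    for (j in moved) {
      seq_p <- purrr::map_dbl(probs, function(p) p$probability[j])
      expect_true(all(diff(seq_p) > 0) || all(diff(seq_p) < 0))
    }
  }
})

test_that("probabilities pushed above one are flagged invalid, direction reported", {
  st <- uniform_strata(0.1, 0.9)
  fit <- fit_inclusion_model(st, "eq1")
  grid <- stratum_grid("eq1")

  # 0.9 * e^0.2 > 1: every died stratum becomes invalid
  report <- validate_probabilities(
    apply_scenario(fit, list(target = "lg1", delta = 0.2)),
    grid,
    baseline = fit
  )
  expect_equal(report$valid, grid$died == 0L)
  expect_equal(
    report$probability[report$died == 1L],
    rep(0.9 * exp(0.2), 5),
    tolerance = 1e-12
  )

  # unshifted parameters on their own fitting strata are all valid
  expect_true(all(validate_probabilities(fit)$valid))

  # a pure intercept decrease lowers every stratum
  down <- validate_probabilities(
    apply_scenario(fit, list(target = "lg0", delta = -0.1)),
    grid,
    baseline = fit
  )
  expect_true(all(down$direction == -1))
  expect_equal(down$probability / down$probability_before,
    rep(exp(-0.1), nrow(grid)),
    tolerance = 1e-12
  )
})

test_that("footnoted scenarios move unshifted ethnicities only through the death effect", {
  st <- uniform_strata(0.1, 0.6)
  fit <- fit_inclusion_model(st, "eq1")
  sc <- scenario_grid("eq1") %>%
    dplyr::filter(target == "la_Asian", level == 100)
  report <- validate_probabilities(
    apply_scenario(fit, sc), stratum_grid("eq1"),
    baseline = fit
  )
  white_died <- dplyr::filter(report, ethnicity == "White", died == 1L)
  expect_equal(
    white_died$probability / white_died$probability_before, exp(-0.15),
    tolerance = 1e-12
  )
  white_surv <- dplyr::filter(report, ethnicity == "White", died == 0L)
  expect_equal(white_surv$direction, 0)
})
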