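# Saturated log-link (log-binomial) model for the probability of
# hospitalisation given ethnic group, survival status and (optionally)
# epidemic wave, fitted from a stratified summary table. Because the model
# is saturated, fitted probabilities equal observed stratum risks exactly
# and every coefficient is a closed-form log risk ratio; inverting the
# predicted probabilities gives the selection weights.

coef_contrasts <- function(model_form) {
  # Each coefficient is a signed sum of cell log-risks; rows are (e, d, w, sign).
  cell <- function(e, d, w, s) tibble::tibble(ethnicity = e, died = d, wave = w, sign = s)
  out <- list(
    lg0 = cell("White", 0L, 1L, 1),
    lg1 = dplyr::bind_rows(cell("White", 1L, 1L, 1), cell("White", 0L, 1L, -1))
  )
  for (e in nonref_ethnicities()) {
    out[[coef_name("la", e)]] <- dplyr::bind_rows(
      cell(e, 0L, 1L, 1), cell("White", 0L, 1L, -1)
    )
    out[[coef_name("lb", e)]] <- dplyr::bind_rows(
      cell(e, 1L, 1L, 1), cell(e, 0L, 1L, -1),
      cell("White", 1L, 1L, -1), cell("White", 0L, 1L, 1)
    )
  }
  if (model_form == "eq2") {
    out$lg2 <- dplyr::bind_rows(cell("White", 0L, 2L, 1), cell("White", 0L, 1L, -1))
    out$lg3 <- dplyr::bind_rows(
      cell("White", 1L, 2L, 1), cell("White", 0L, 2L, -1),
      cell("White", 1L, 1L, -1), cell("White", 0L, 1L, 1)
    )
    for (e in nonref_ethnicities()) {
      out[[coef_name("lc", e)]] <- dplyr::bind_rows(
        cell(e, 0L, 2L, 1), cell(e, 0L, 1L, -1),
        cell("White", 0L, 2L, -1), cell("White", 0L, 1L, 1)
      )
      out[[coef_name("ld", e)]] <- dplyr::bind_rows(
        cell(e, 1L, 2L, 1), cell(e, 0L, 2L, -1),
        cell(e, 1L, 1L, -1), cell(e, 0L, 1L, 1),
        cell("White", 1L, 2L, -1), cell("White", 0L, 2L, 1),
        cell("White", 1L, 1L, 1), cell("White", 0L, 1L, -1)
      )
    }
  }
  out
}

#' Fit the saturated selection model from a strata table
#'
#' Fits the log-link risk model for P(hospitalised | ethnicity, died, wave)
#' by the closed-form saturated estimator: each coefficient is the signed
#' combination of cell log-risks that makes the fitted probability of every
#' stratum equal its observed risk exactly. Exponentiated coefficients are
#' risk ratios (e.g. the death main effect is the hospitalisation risk
#' ratio, died versus survived, among the reference group in wave 1).
#'
#' Standard errors come from the observed information of the log-binomial
#' likelihood: `var(ln p) = (1 - p) / (n p)` per cell, summed over the
#' independent cells in each coefficient's contrast, and reported on the
#' exponentiated scale by the delta method.
#'
#' @param strata Strata table from [build_strata_from_marginals()]: one row
#'   per (ethnicity, died, wave) with `n_at_risk`, `n_hospitalised`,
#'   `risk`. `"eq1"` needs the 10 wave-1 cells, `"eq2"` all 20.
#' @param model_form `"eq1"` (ethnicity x death) or `"eq2"` (adds wave main
#'   effect and all wave interactions).
#' @return An object of class `inclusion_model`: log-scale coefficients,
#'   their log-scale and exponentiated-scale standard errors, and the
#'   fitting strata. Methods: [predict_probability()], [derive_weights()],
#'   [tidy.inclusion_model()], [glance.inclusion_model()].
#' @export
#' @examples
#' strata <- tibble::tibble(
#'   ethnicity = rep(ethnicity_levels(), each = 2),
#'   wave = 1, died = rep(0:1, 5),
#'   n_at_risk = rep(c(10000, 100), 5),
#'   n_hospitalised = c(20, 90, 30, 85, 25, 88, 22, 90, 15, 92)
#' )
#' strata$risk <- strata$n_hospitalised / strata$n_at_risk
#' fit <- fit_inclusion_model(strata, "eq1")
#' tidy(fit)
fit_inclusion_model <- function(strata, model_form = c("eq1", "eq2")) {
  model_form <- match.arg(model_form)
  strata <- normalise_strata(strata, model_form)

  zero <- dplyr::filter(strata, .data$risk <= 0)
  if (nrow(zero) > 0) {
    cpw_model_error(
      "Non-identifiable coefficient: observed risk is 0 in stratum (",
      zero$ethnicity[1L], ", died = ", zero$died[1L], ", wave = ",
      zero$wave[1L], ")."
    )
  }
  over <- dplyr::filter(strata, .data$risk > 1)
  if (nrow(over) > 0) {
    cpw_evidence_error(
      "Observed risk exceeds 1 in stratum (", over$ethnicity[1L],
      ", died = ", over$died[1L], ", wave = ", over$wave[1L],
      "); the marginal counts (or pseudo-counts) are inconsistent."
    )
  }

  strata <- dplyr::mutate(
    strata,
    log_risk = log(.data$risk),
    var_log_risk = (1 - .data$risk) / (.data$n_at_risk * .data$risk)
  )
  contrasts <- coef_contrasts(model_form)
  key <- paste(strata$ethnicity, strata$died, strata$wave)
  combine <- function(contrast, col) {
    idx <- match(
      paste(contrast$ethnicity, contrast$died, contrast$wave), key
    )
    sum(contrast$sign * strata[[col]][idx])
  }
  coefs <- vapply(contrasts, combine, numeric(1), col = "log_risk")
  vars <- vapply(
    contrasts,
    function(ct) sum(abs(ct$sign) * strata$var_log_risk[
      match(paste(ct$ethnicity, ct$died, ct$wave), key)
    ]),
    numeric(1)
  )
  se_log <- sqrt(vars)

  structure(
    list(
      model_form = model_form,
      coefficients = coefs,
      se_log = se_log,
      se_exp = exp(coefs) * se_log,
      strata = strata,
      misspecified = FALSE
    ),
    class = "inclusion_model"
  )
}

normalise_strata <- function(strata, model_form) {
  required <- c("ethnicity", "died", "n_at_risk", "n_hospitalised")
  missing <- setdiff(required, names(strata))
  if (length(missing) > 0) {
    cpw_config_error("`strata` lacks columns: ", paste(missing, collapse = ", "), ".")
  }
  if (!"wave" %in% names(strata)) strata$wave <- 1L
  strata <- strata %>%
    tibble::as_tibble() %>%
    dplyr::mutate(
      ethnicity = as_ethnicity(.data$ethnicity),
      died = as.integer(.data$died),
      wave = as.integer(.data$wave),
      risk = .data$n_hospitalised / .data$n_at_risk
    )
  needed <- stratum_grid(model_form)
  have <- paste(strata$ethnicity, strata$died, strata$wave)
  want <- paste(needed$ethnicity, needed$died, needed$wave)
  if (anyDuplicated(have) > 0) {
    cpw_config_error("`strata` contains duplicated (ethnicity, died, wave) cells.")
  }
  if (!all(want %in% have)) {
    miss <- needed[!want %in% have, ][1L, ]
    cpw_config_error(
      "Strata table is missing the cell (", miss$ethnicity, ", died = ",
      miss$died, ", wave = ", miss$wave, ") required by model form."
    )
  }
  strata <- strata[have %in% want, , drop = FALSE]
  if (any(strata$n_at_risk <= 0)) {
    cpw_config_error("Every required stratum must have `n_at_risk` > 0.")
  }
  dplyr::arrange(strata, .data$ethnicity, .data$wave, .data$died)
}

#' @export
print.inclusion_model <- function(x, ...) {
  cat("Saturated log-link selection model (", x$model_form, "), ",
    length(x$coefficients), " coefficients",
    if (isTRUE(x$misspecified)) " [misspecification applied]", "\n",
    sep = ""
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Iterative log-binomial fit of the selection model
#'
#' Maximum-likelihood log-binomial fit of the same model via
#' [stats::glm()] with a log link, started from a valid interior point.
#' On a saturated strata table this converges to the closed-form estimator
#' of [fit_inclusion_model()] (agreement to at least 1e-8); it exists as an
#' independent fitting route and for non-saturated extensions.
#'
#' @inheritParams fit_inclusion_model
#' @return An `inclusion_model` object (coefficients mapped to the same
#'   naming as the closed form; standard errors from the glm information
#'   matrix on the log scale).
#' @export
fit_inclusion_glm <- function(strata, model_form = c("eq1", "eq2")) {
  model_form <- match.arg(model_form)
  strata <- normalise_strata(strata, model_form)
  df <- strata %>%
    dplyr::mutate(
      ethnicity = factor(.data$ethnicity, levels = ethnicity_levels()),
      died = .data$died,
      wave2 = as.integer(.data$wave == 2L)
    )
  fml <- if (model_form == "eq1") {
    risk ~ ethnicity * died
  } else {
    risk ~ ethnicity * died * wave2
  }
  nterms <- if (model_form == "eq1") 10L else 20L
  # start at a uniformly low risk so every linear predictor is valid (< 0)
  start <- c(log(min(df$risk)) - 1, rep(0, nterms - 1L))
  fit <- suppressWarnings(stats::glm(
    fml,
    family = stats::binomial(link = "log"), data = df,
    weights = df$n_at_risk, start = start,
    control = stats::glm.control(epsilon = 1e-12, maxit = 200)
  ))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  map <- glm_name_map(model_form)
  coefs <- stats::setNames(co[map], names(map))
  se_log <- stats::setNames(se[map], names(map))
  structure(
    list(
      model_form = model_form,
      coefficients = coefs,
      se_log = se_log,
      se_exp = exp(coefs) * se_log,
      strata = strata,
      misspecified = FALSE,
      glm_fit = fit
    ),
    class = "inclusion_model"
  )
}

glm_name_map <- function(model_form) {
  map <- c(lg0 = "(Intercept)", lg1 = "died")
  for (e in nonref_ethnicities()) {
    map[coef_name("la", e)] <- paste0("ethnicity", e)
    map[coef_name("lb", e)] <- paste0("ethnicity", e, ":died")
  }
  if (model_form == "eq2") {
    map <- c(map, lg2 = "wave2", lg3 = "died:wave2")
    for (e in nonref_ethnicities()) {
      map[coef_name("lc", e)] <- paste0("ethnicity", e, ":wave2")
      map[coef_name("ld", e)] <- paste0("ethnicity", e, ":died:wave2")
    }
  }
  map
}

#' Predict per-stratum selection probabilities
#'
#' Evaluates `exp(eta)` where `eta` is the model's linear predictor for
#' each requested stratum: intercept + death main effect + ethnicity main
#' effect + ethnicity-by-death interaction (plus, under `"eq2"`, the wave
#' main effect and its interactions). The reference group (White, survived,
#' wave 1) contributes the intercept only.
#'
#' @param params An `inclusion_model`.
#' @param strata Data frame with columns `ethnicity`, `died` and (for
#'   `"eq2"`) `wave`; a missing wave column is taken as wave 1.
#' @param check If `TRUE` (default), predicted probabilities above 1 raise
#'   an invalid-probability error; `FALSE` returns them unclamped (used by
#'   the misspecification validity report).
#' @return Numeric vector of probabilities, one per row of `strata`.
#' @export
predict_probability <- function(params, strata, check = TRUE) {
  stopifnot(inherits(params, "inclusion_model"))
  if (!"wave" %in% names(strata)) strata$wave <- 1L
  eth <- as_ethnicity(strata$ethnicity)
  died <- as.integer(strata$died)
  wave2 <- as.integer(strata$wave == 2L)
  if (params$model_form == "eq1" && any(wave2 == 1L)) {
    cpw_config_error("Model form `eq1` cannot predict wave-2 strata; fit `eq2`.")
  }
  co <- params$coefficients
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
  p <- exp(eta)
  if (check) {
    if (any(p > 1 + 1e-12)) {
      bad <- which(p > 1 + 1e-12)[1L]
      cpw_model_error(
        "Predicted probability exceeds 1 (", format(p[bad]), ") for stratum (",
        eth[bad], ", died = ", died[bad], ", wave = ", strata$wave[bad],
        "); the parameter set is misspecified beyond validity."
      )
    }
    p <- pmin(p, 1) # absorb rounding overshoot at the boundary
  }
  p
}

#' Attach inverse probability of selection weights to a cohort
#'
#' Looks up each admission's stratum (ethnicity, died, wave), predicts its
#' selection probability under the fitted model, and attaches
#' `weight = 1 / probability`. Weighting the hospitalised cohort this way
#' emulates the unselected source population (the IPW pseudo-population):
#' the weight-sum within a stratum estimates that stratum's full-population
#' size.
#'
#' @param params An `inclusion_model`.
#' @param cohort Cohort tibble with columns `ethnicity`, `died` and (for
#'   `"eq2"`) `wave`.
#' @return The cohort with a `weight` column (all `>= 1` for valid
#'   probabilities).
#' @export
derive_weights <- function(params, cohort) {
  p <- predict_probability(params, cohort, check = TRUE)
  if (any(p <= 0)) {
    cpw_model_error("Selection probability must be in (0, 1] to derive weights.")
  }
  dplyr::mutate(cohort, weight = 1 / p)
}
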