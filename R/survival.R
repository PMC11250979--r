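# Weighted cause-specific Cox models for death with discharge as a
# competing event. Discharge (and administrative censoring) terminate
# follow-up without a death event; case weights enter the partial
# likelihood and the variance is the weighted robust (sandwich) estimator.

default_covariates <- function() {
  c(
    "age", "sex", "imd_quintile", "dnr", "cardiovascular", "copd",
    "diabetes", "liver", "kidney"
  )
}

#' Weighted cause-specific Cox model for death
#'
#' Fits a Cox proportional hazards model for time to death in which
#' discharge is a competing event: discharged (and censored) admissions
#' leave the risk set at their event time without contributing a death.
#' Case weights (inverse probability of selection weights) multiply each
#' record's contribution to the partial likelihood, and standard errors are
#' always the robust sandwich estimator, which remains valid under
#' weighting.
#'
#' @param cohort Cohort tibble: `time_to_event` (> 0), `event_type`
#'   (`"death"`, `"discharge"`, `"censored"`), `ethnicity`, the baseline
#'   covariates, and `weight` (used when `use_weights = TRUE`; defaults
#'   to 1).
#' @param terms Character vector of model terms; `"ethnicity"` enters with
#'   White as reference and `"imd_quintile"` as a categorical quintile by
#'   default.
#' @param use_weights Apply the cohort's `weight` column.
#' @param ties Tie handling for the partial likelihood: `"efron"` (default)
#'   or `"breslow"`.
#' @param imd_as_factor Enter IMD quintile as 4 indicator terms (default)
#'   rather than a linear score.
#' @return A `cox_result`: the [survival::coxph()] fit plus a tidy
#'   per-term table of log hazard ratios, robust SEs, hazard ratios, 95%
#'   normal-approximation CIs (`exp(log HR +/- 1.96 robust SE)`) and
#'   p-values, with metadata (`n`, `n_events`, weighting flag, ties).
#' @export
fit_weighted_cox <- function(cohort, terms = "ethnicity", use_weights = FALSE,
                             ties = c("efron", "breslow"),
                             imd_as_factor = TRUE) {
  ties <- match.arg(ties)
  if (!all(c("time_to_event", "event_type") %in% names(cohort))) {
    cpw_config_error("`cohort` needs `time_to_event` and `event_type` columns.")
  }
  if (any(cohort$time_to_event <= 0)) {
    cpw_config_error("All `time_to_event` values must be positive.")
  }
  if (!all(cohort$event_type %in% c("death", "discharge", "censored"))) {
    cpw_config_error("`event_type` must be one of death, discharge, censored.")
  }
  n_events <- sum(cohort$event_type == "death")
  if (n_events < 1) {
    cpw_model_error("Cannot fit the death hazard: no death events in the cohort.")
  }
  missing <- setdiff(terms, names(cohort))
  if (length(missing) > 0) {
    cpw_config_error("Model terms absent from cohort: ", paste(missing, collapse = ", "), ".")
  }

  df <- tibble::as_tibble(cohort)
  if ("ethnicity" %in% terms) {
    df$ethnicity <- droplevels(as_ethnicity(df$ethnicity))
  }
  if ("imd_quintile" %in% terms && imd_as_factor) {
    df$imd_quintile <- factor(df$imd_quintile, levels = 1:5)
  }
  # constant terms cannot be estimated; a single-level factor (e.g. an
  # ethnicity-only cohort with one group) is dropped with a warning
  keep <- vapply(terms, function(t) {
    v <- df[[t]]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  if (any(!keep)) {
    rlang::warn(paste0(
      "Dropping constant model term(s): ", paste(terms[!keep], collapse = ", "), "."
    ))
    terms <- terms[keep]
  }
  if (length(terms) == 0L) {
    rlang::warn("No estimable model terms; returning an empty result.")
    return(empty_cox_result(df, n_events, use_weights, ties))
  }

  if (use_weights) {
    if (!"weight" %in% names(df) || any(is.na(df$weight))) {
      cpw_config_error("`use_weights = TRUE` requires a complete `weight` column.")
    }
    if (any(df$weight <= 0)) cpw_config_error("Weights must be positive.")
  }
  df$.wt <- if (use_weights) df$weight else rep(1, nrow(df))
  df$.status <- as.integer(df$event_type == "death")

  fml <- stats::as.formula(paste(
    "survival::Surv(time_to_event, .status) ~", paste(terms, collapse = " + ")
  ))
  fit <- survival::coxph(
    fml,
    data = df, weights = .wt, ties = ties, robust = TRUE,
    x = FALSE, y = FALSE
  )
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    cpw_model_error(
      "Collinear or degenerate model term(s): ", paste(bad, collapse = ", "), "."
    )
  }
  log_hr <- stats::coef(fit)
  robust_se <- sqrt(diag(fit$var)) # robust variance (robust = TRUE)
  z <- log_hr / robust_se
  table <- tibble::tibble(
    term = names(log_hr),
    log_hr = unname(log_hr),
    robust_se = unname(robust_se),
    hazard_ratio = exp(unname(log_hr)),
    ci_lower = exp(unname(log_hr) - 1.96 * unname(robust_se)),
    ci_upper = exp(unname(log_hr) + 1.96 * unname(robust_se)),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(
    list(
      table = table,
      fit = fit,
      n = nrow(df),
      n_events = n_events,
      use_weights = use_weights,
      ties = ties,
      converged = TRUE
    ),
    class = "cox_result"
  )
}

empty_cox_result <- function(df, n_events, use_weights, ties) {
  structure(
    list(
      table = tibble::tibble(
        term = character(), log_hr = numeric(), robust_se = numeric(),
        hazard_ratio = numeric(), ci_lower = numeric(), ci_upper = numeric(),
        p_value = numeric()
      ),
      fit = NULL, n = nrow(df), n_events = n_events,
      use_weights = use_weights, ties = ties, converged = NA
    ),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(
    "Cause-specific Cox model for death (discharge competing), ",
    if (x$use_weights) "IPW-weighted" else "unweighted",
    ", robust SEs; n = ", x$n, ", deaths = ", x$n_events, "\n",
    sep = ""
  )
  print(x$table, n = Inf)
  invisible(x)
}

#' Run the three standard model iterations
#'
#' Fits the analysis' three nested specifications on one cohort:
#' \describe{
#'   \item{unadjusted}{ethnicity only;}
#'   \item{adjusted}{ethnicity plus the nine baseline covariates;}
#'   \item{weighted}{the adjusted model with inverse probability of
#'     selection weights applied.}
#' }
#' Comparing the three separates confounding by measured covariates
#' (unadjusted versus adjusted) from selection/collider bias (adjusted
#' versus weighted).
#'
#' @param cohort Cohort tibble; must carry a `weight` column for the
#'   weighted iteration (see [derive_weights()]).
#' @param covariates Covariate terms for iterations 2--3 (defaults to the
#'   nine baseline covariates).
#' @param ties Passed to [fit_weighted_cox()].
#' @return A named list of three `cox_result`s
#'   (`unadjusted`, `adjusted`, `weighted`), class `model_iterations`.
#' @export
run_model_iterations <- function(cohort, covariates = default_covariates(),
                                 ties = "efron") {
  if (!"weight" %in% names(cohort) || anyNA(cohort$weight)) {
    cpw_config_error(
      "The weighted iteration needs a complete `weight` column; run ",
      "`derive_weights()` first (or set weights to 1 explicitly)."
    )
  }
  covariates <- intersect(covariates, names(cohort))
  structure(
    list(
      unadjusted = fit_weighted_cox(cohort,
        terms = "ethnicity", use_weights = FALSE, ties = ties
      ),
      adjusted = fit_weighted_cox(cohort,
        terms = c("ethnicity", covariates), use_weights = FALSE, ties = ties
      ),
      weighted = fit_weighted_cox(cohort,
        terms = c("ethnicity", covariates), use_weights = TRUE, ties = ties
      )
    ),
    class = "model_iterations"
  )
}

#' @export
print.model_iterations <- function(x, ...) {
  print(summarise_hr(x), n = Inf)
  invisible(x)
}

#' Forest-style hazard ratio summary
#'
#' One row per (ethnic group, model iteration): hazard ratio, 95% CI,
#' p-value, and a formatted `"HR = h (l, u), p = p"` label.
#'
#' @param results A `model_iterations` object or named list of
#'   `cox_result`s.
#' @return Tibble with columns `iteration`, `ethnicity`, `hazard_ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`, `log_hr`, `robust_se`, `label`.
#' @export
summarise_hr <- function(results) {
  if (inherits(results, "cox_result")) results <- list(model = results)
  rows <- purrr::imap_dfr(unclass(results), function(res, name) {
    tab <- dplyr::filter(res$table, startsWith(.data$term, "ethnicity"))
    if (nrow(tab) == 0) {
      return(tibble::tibble())
    }
    tab %>%
      dplyr::mutate(
        iteration = name,
        ethnicity = sub("^ethnicity", "", .data$term),
        .before = 1L
      ) %>%
      dplyr::select(-"term")
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      iteration = character(), ethnicity = character(),
      hazard_ratio = numeric(), ci_lower = numeric(), ci_upper = numeric(),
      p_value = numeric(), log_hr = numeric(), robust_se = numeric(),
      label = character()
    ))
  }
  rows %>%
    dplyr::mutate(label = format_hr(
      .data$hazard_ratio, .data$ci_lower, .data$ci_upper, .data$p_value
    )) %>%
    dplyr::select(
      "iteration", "ethnicity", "hazard_ratio", "ci_lower", "ci_upper",
      "p_value", "log_hr", "robust_se", "label"
    )
}

#' Format a hazard ratio in the conventional reporting style
#'
#' @param hr,lower,upper,p Numeric vectors.
#' @return Character vector like `"HR = 1.06 (0.56, 2.00), p = 0.851"`.
#' @export
format_hr <- function(hr, lower, upper, p) {
  sprintf(
    "HR = %.2f (%.2f, %.2f), p = %.3f",
    hr, lower, upper, p
  )
}
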