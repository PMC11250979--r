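# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted selection model
#'
#' @param x An `inclusion_model`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate` (log
#'   scale), `exp_estimate` (the risk-ratio scale the model is reported
#'   on), `se_exp`, `se_log`.
#' @method tidy inclusion_model
#' @export
tidy.inclusion_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    exp_estimate = unname(exp(x$coefficients)),
    se_exp = unname(x$se_exp),
    se_log = unname(x$se_log)
  )
}

#' @rdname tidy.inclusion_model
#' @method glance inclusion_model
#' @export
glance.inclusion_model <- function(x, ...) {
  tibble::tibble(
    model_form = x$model_form,
    n_coefficients = length(x$coefficients),
    n_strata = if (is.null(x$strata)) NA_integer_ else nrow(x$strata),
    misspecified = isTRUE(x$misspecified)
  )
}

#' Tidy a weighted Cox fit
#'
#' @param x A `cox_result`.
#' @param ... Unused.
#' @return The per-term table: `term`, `log_hr`, `robust_se`,
#'   `hazard_ratio`, 95% CI bounds and `p_value`.
#' @method tidy cox_result
#' @export
tidy.cox_result <- function(x, ...) {
  x$table
}

#' @rdname tidy.cox_result
#' @method glance cox_result
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, weighted = x$use_weights,
    ties = x$ties, converged = x$converged
  )
}

#' Tidy the three model iterations
#'
#' @param x A `model_iterations` list.
#' @param ... Unused.
#' @return The forest-style ethnicity summary of [summarise_hr()].
#' @method tidy model_iterations
#' @export
tidy.model_iterations <- function(x, ...) {
  summarise_hr(x)
}

#' Tidy a misspecification sweep
#'
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @return The long results table keyed by (scenario, ethnicity).
#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) {
  x$results
}
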