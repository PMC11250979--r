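# Delimited-text interfaces: marginal summaries and cohorts as CSV with
# documented headers, fitted parameters as JSON.

summary_cols <- function() {
  c("ethnicity", "wave", "n_total", "n_hospitalised", "n_died")
}

cohort_required_cols <- function() {
  c("ethnicity", "wave", "time_to_event", "event_type")
}

#' Read / write a marginal summary table
#'
#' CSV with columns `ethnicity`, `wave`, `n_total`, `n_hospitalised`,
#' `n_died` -- one row per (ethnic group, wave), as an external published
#' analysis would report.
#'
#' @param path File path.
#' @return `read_summary_csv()` returns the summary tibble.
#' @export
read_summary_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(summary_cols(), names(x))
  if (length(missing) > 0) {
    cpw_config_error(
      "Summary CSV lacks columns: ", paste(missing, collapse = ", "), "."
    )
  }
  dplyr::mutate(x, ethnicity = as_ethnicity(.data$ethnicity))
}

#' @rdname read_summary_csv
#' @param x Summary tibble.
#' @export
write_summary_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read / write a hospitalised cohort table
#'
#' CSV with one admission per row. Required columns: `ethnicity`, `wave`,
#' `time_to_event` (days, > 0), `event_type` (`death` / `discharge` /
#' `censored`); optional: `died` (derived from `event_type` when absent),
#' `weight`, and the nine baseline covariates (`age`, `sex`,
#' `imd_quintile`, `dnr`, `cardiovascular`, `copd`, `diabetes`, `liver`,
#' `kidney`).
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(cohort_required_cols(), names(x))
  if (length(missing) > 0) {
    cpw_config_error(
      "Cohort CSV lacks columns: ", paste(missing, collapse = ", "), "."
    )
  }
  x <- dplyr::mutate(x, ethnicity = as_ethnicity(.data$ethnicity))
  ensure_died(x)
}

#' @rdname read_cohort_csv
#' @param x Cohort tibble.
#' @export
write_cohort_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

ensure_died <- function(cohort) {
  if (!"died" %in% names(cohort)) {
    cohort$died <- as.integer(cohort$event_type == "death")
  }
  cohort
}

#' Serialise fitted selection-model parameters to JSON
#'
#' Writes one record per coefficient: name, log-scale value, exponentiated
#' value, and the exponentiated-scale standard error.
#'
#' @param params An `inclusion_model`.
#' @param path File path.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "inclusion_model"))
  out <- list(
    model_form = params$model_form,
    misspecified = isTRUE(params$misspecified),
    coefficients = purrr::map(names(params$coefficients), function(nm) {
      list(
        term = nm,
        log_value = unname(params$coefficients[[nm]]),
        exp_value = unname(exp(params$coefficients[[nm]])),
        se_exp = unname(params$se_exp[[nm]])
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @return `read_params_json()` returns an `inclusion_model` (without
#'   fitting strata).
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path)
  coefs <- vapply(raw$coefficients, function(x) x$log_value, numeric(1))
  names(coefs) <- vapply(raw$coefficients, function(x) x$term, character(1))
  se_exp <- vapply(raw$coefficients, function(x) x$se_exp %||% NA_real_, numeric(1))
  names(se_exp) <- names(coefs)
  structure(
    list(
      model_form = raw$model_form,
      coefficients = coefs,
      se_log = se_exp / exp(coefs),
      se_exp = se_exp,
      strata = NULL,
      misspecified = isTRUE(raw$misspecified)
    ),
    class = "inclusion_model"
  )
}
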