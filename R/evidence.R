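# External summary evidence: split marginal (ethnicity x wave) counts into
# the survival-status strata the selection model needs, and the risk / risk
# ratio / log-difference calculus used to calibrate misspecification.

#' Build survival-status strata from marginal summary counts
#'
#' External publications typically report, per ethnic group and wave, only
#' the population denominator, the number hospitalised and the number who
#' died -- without cross-tabulating hospitalisation by survival. This
#' function reconstructs the (ethnicity, died, wave) strata by assuming a
#' fixed fraction of deaths were hospitalised before death (0.90 by
#' default, applied identically to every ethnic group).
#'
#' For each marginal row the died stratum gets `n_at_risk = n_died` and
#' `n_hospitalised = fraction * n_died`; the survived stratum gets
#' `n_at_risk = n_total - n_died` and the remaining hospitalisations.
#' Counts are kept fractional by default because the saturated fit uses
#' risks, not integers; `rounding = "integer"` rounds the died-stratum
#' hospitalisation count for count-based fitters.
#'
#' @param marginals Tibble with columns `ethnicity`, `wave`, `n_total`,
#'   `n_hospitalised`, `n_died` (as from [derive_external_summary()] or
#'   [read_summary_csv()]).
#' @param hospitalised_death_fraction Assumed P(hospitalised | died), in
#'   `[0, 1]`.
#' @param rounding `"none"` (fractional pseudo-counts, default) or
#'   `"integer"`.
#' @return Tibble with one row per (ethnicity, wave, died): `n_at_risk`,
#'   `n_hospitalised` and the derived `risk`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   ethnicity = "White", wave = 1,
#'   n_total = 1000, n_hospitalised = 100, n_died = 100
#' )
#' build_strata_from_marginals(m, 0.9)
build_strata_from_marginals <- function(marginals,
                                        hospitalised_death_fraction = 0.90,
                                        rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  f <- hospitalised_death_fraction
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    cpw_config_error("`hospitalised_death_fraction` must be a probability in [0, 1].")
  }
  required <- c("ethnicity", "wave", "n_total", "n_hospitalised", "n_died")
  missing <- setdiff(required, names(marginals))
  if (length(missing) > 0) {
    cpw_config_error("`marginals` lacks columns: ", paste(missing, collapse = ", "), ".")
  }
  bad <- dplyr::filter(
    marginals,
    .data$n_died > .data$n_total | .data$n_hospitalised > .data$n_total
  )
  if (nrow(bad) > 0) {
    cpw_evidence_error(
      "Marginal counts exceed the population denominator in stratum (",
      bad$ethnicity[1L], ", wave = ", bad$wave[1L], ")."
    )
  }

  strata <- marginals %>%
    dplyr::mutate(
      hosp_died = if (rounding == "integer") round(f * .data$n_died) else f * .data$n_died
    ) %>%
    dplyr::mutate(
      hosp_survived = .data$n_hospitalised - .data$hosp_died
    )

  neg <- dplyr::filter(strata, .data$hosp_survived < 0)
  if (nrow(neg) > 0) {
    cpw_evidence_error(
      "Implied survivor hospitalisation count is negative in stratum (",
      neg$ethnicity[1L], ", wave = ", neg$wave[1L], "): ",
      format(neg$n_hospitalised[1L]), " hospitalised < ",
      format(neg$hosp_died[1L]), " assumed hospitalised deaths. ",
      "Lower `hospitalised_death_fraction` or check the marginal counts."
    )
  }

  strata %>%
    tidyr::pivot_longer(
      c("hosp_died", "hosp_survived"),
      names_to = "status", values_to = "n_hosp_stratum"
    ) %>%
    dplyr::mutate(
      died = as.integer(.data$status == "hosp_died"),
      n_at_risk = ifelse(.data$died == 1L, .data$n_died, .data$n_total - .data$n_died)
    ) %>%
    dplyr::transmute(
      ethnicity = as_ethnicity(.data$ethnicity),
      wave = as.integer(.data$wave),
      died = .data$died,
      n_at_risk = .data$n_at_risk,
      n_hospitalised = .data$n_hosp_stratum,
      risk = ifelse(.data$n_at_risk > 0,
        .data$n_hospitalised / .data$n_at_risk, NA_real_
      )
    ) %>%
    dplyr::arrange(.data$ethnicity, .data$wave, .data$died)
}

#' Risk of an event
#'
#' Exact quotient `cases / population`, vectorised. A zero denominator is an
#' error (even with zero cases): the risk is undefined, not zero.
#'
#' @param cases Non-negative event count(s).
#' @param population Positive denominator(s).
#' @return Probability vector.
#' @export
compute_risk <- function(cases, population) {
  if (any(cases < 0 | population < 0, na.rm = TRUE)) {
    cpw_config_error("Counts must be non-negative.")
  }
  if (any(population == 0, na.rm = TRUE)) {
    cpw_evidence_error("Risk undefined: zero population denominator.")
  }
  cases / population
}

#' Risk ratio against a reference group
#'
#' @param risk,reference_risk Probabilities; `reference_risk` must be
#'   strictly positive.
#' @return Positive ratio(s) `risk / reference_risk`.
#' @export
compute_risk_ratio <- function(risk, reference_risk) {
  if (any(reference_risk <= 0, na.rm = TRUE)) {
    cpw_evidence_error("Risk ratio undefined: non-positive reference risk.")
  }
  risk / reference_risk
}

#' Difference of natural logarithms
#'
#' `ln(metric_local) - ln(metric_reference)`, the scale on which
#' misspecification shifts to the selection-model coefficients are
#' expressed. Antisymmetric under swapping the arguments.
#'
#' @param metric_local,metric_reference Strictly positive values (risks or
#'   risk ratios).
#' @return Real log-difference(s).
#' @export
compare_ln <- function(metric_local, metric_reference) {
  if (any(metric_local <= 0 | metric_reference <= 0, na.rm = TRUE)) {
    cpw_config_error("`compare_ln()` requires strictly positive inputs.")
  }
  log(metric_local) - log(metric_reference)
}

#' Local-versus-reference risk comparison table
#'
#' Adds the log-difference column to a table of paired local and reference
#' metrics (risks or risk ratios). Each row's `ln_diff` quantifies how far
#' a locally observed quantity sits from the external source that the
#' selection model was fitted to, and so suggests the size of
#' misspecification shift worth exploring for the coefficient it informs.
#'
#' @param data Data frame with columns `metric_local` and
#'   `metric_reference` (plus any labelling columns, carried through).
#' @return The input as a tibble with an appended `ln_diff` column.
#' @export
risk_comparison <- function(data) {
  required <- c("metric_local", "metric_reference")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    cpw_config_error("`data` lacks columns: ", paste(missing, collapse = ", "), ".")
  }
  tibble::as_tibble(data) %>%
    dplyr::mutate(ln_diff = compare_ln(.data$metric_local, .data$metric_reference))
}

#' Packaged local-versus-national comparison inputs
#'
#' Loads the bundled comparison table of published hospitalisation risks
#' and risk ratios: a national reference analysis versus a London hospital
#' catchment area, per ethnic group and survival status. These are the
#' inputs of the misspecification-calibration calculus; see
#' [external_comparison_summary()] for the derived quantities.
#'
#' @param path Optional CSV with the same columns as the packaged file.
#' @return Tibble with columns `quantity`, `metric` (`"risk"` or `"rr"`),
#'   `reference_risk`, `reference_rr`, `local_risk`, `local_rr`, `informs`
#'   (the selection-model coefficient the row's log-difference calibrates).
#' @export
load_external_comparison <- function(path = NULL) {
  path <- path %||% system.file(
    "extdata", "external_risk_comparison.csv",
    package = "collideripw", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE)
}

#' Local-versus-reference comparison calculus
#'
#' Recomputes, from a comparison input table, the reference risk ratios
#' (each ethnic group's risk against the White risk) and the
#' log-differences between local and reference metrics: risks compared on
#' the risk scale, group effects on the risk-ratio scale. The resulting
#' `ln_diff` values are the evidence-suggested misspecification shifts for
#' the coefficients named in `informs`.
#'
#' @param comparison Tibble as returned by [load_external_comparison()].
#' @return The input with appended `rr_reference_recomputed` (where a White
#'   reference risk is present) and `ln_diff` columns.
#' @export
external_comparison_summary <- function(comparison = load_external_comparison()) {
  white <- dplyr::filter(comparison, .data$quantity == "white")
  ref_white <- if (nrow(white) == 1) white$reference_risk else NA_real_
  comparison %>%
    dplyr::mutate(
      rr_reference_recomputed = dplyr::if_else(
        !is.na(.data$reference_rr) & !is.na(ref_white) & .data$quantity != "death",
        compute_risk_ratio(.data$reference_risk, ref_white),
        NA_real_
      ),
      metric_local = dplyr::if_else(
        .data$metric == "rr", .data$local_rr, .data$local_risk
      ),
      metric_reference = dplyr::if_else(
        .data$metric == "rr", .data$reference_rr, .data$reference_risk
      ),
      ln_diff = compare_ln(.data$metric_local, .data$metric_reference)
    )
}
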