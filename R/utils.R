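# Shared vocabulary: ethnic-group levels, coefficient naming, stratum grids,
# and classed error conditions used across the pipeline.

#' Ethnic group categories
#'
#' The five collapsed ethnic-group categories used throughout the package,
#' with `"White"` as the reference level of every model.
#'
#' @return Character vector of the five category labels.
#' @export
ethnicity_levels <- function() {
  c("White", "Black", "Asian", "Mixed/Other", "Unknown")
}

# Non-reference categories, in the order the selection-model subscripts run.
nonref_ethnicities <- function() ethnicity_levels()[-1]

coef_name <- function(prefix, ethnicity) paste(prefix, ethnicity, sep = "_")

as_ethnicity <- function(x) {
  out <- factor(as.character(x), levels = ethnicity_levels())
  if (anyNA(out) && !anyNA(x)) {
    bad <- setdiff(unique(as.character(x)), ethnicity_levels())
    cpw_config_error(
      "Unknown ethnicity category: ", paste(bad, collapse = ", "),
      ". Expected one of: ", paste(ethnicity_levels(), collapse = ", "), "."
    )
  }
  out
}

#' Stratum grid for a selection-model form
#'
#' Enumerates the (ethnicity, died, wave) cells that a saturated selection
#' model of the given form is fitted to: 10 cells for `"eq1"` (single wave),
#' 20 for `"eq2"` (two waves).
#'
#' @param model_form `"eq1"` (ethnicity x survival status) or `"eq2"`
#'   (ethnicity x survival status x wave).
#' @return A tibble with columns `ethnicity`, `died`, `wave`.
#' @export
stratum_grid <- function(model_form = c("eq1", "eq2")) {
  model_form <- match.arg(model_form)
  waves <- if (model_form == "eq2") c(1L, 2L) else 1L
  tidyr::expand_grid(
    ethnicity = factor(ethnicity_levels(), levels = ethnicity_levels()),
    died = c(0L, 1L),
    wave = waves
  )
}

# --- classed conditions -----------------------------------------------------

cpw_abort <- function(class, ...) {
  msg <- paste0(...)
  rlang::abort(msg, class = c(class, "collideripw_error"))
}

cpw_config_error <- function(...) cpw_abort("collideripw_config_error", ...)
cpw_evidence_error <- function(...) cpw_abort("collideripw_evidence_error", ...)
cpw_model_error <- function(...) cpw_abort("collideripw_model_error", ...)

`%||%` <- rlang::`%||%`
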