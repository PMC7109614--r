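#' Load a spirometry reference-equation set
#'
#' A reference-equation set maps (sex, ancestry group, age, height) to
#' predicted FEV1, predicted FVC and the predicted FEV1/FVC ratio, plus their
#' lower limits of normal (LLN), computed as predicted minus 1.645 times the
#' stored standard error of estimate (SEE) — the one-sided 5th percentile
#' under the usual normal-residual assumption. Each (sex, group) pair has its
#' own coefficient row; evaluation outside the stated age/height validity
#' ranges is an error, never an extrapolation.
#'
#' The bundled default (`reference_equations_synthetic.csv`) is a
#' package-constructed synthetic all-age set with realistic magnitudes — it is
#' *not* transcribed from a published population study and is intended to be
#' replaced by a locally appropriate published set via the config.
#'
#' @param path CSV file with columns `source, sex, group, age_min, age_max,
#'   height_min, height_max, ratio_b0, ratio_b_age, ratio_see, fev1_b0,
#'   fev1_b_age, fev1_b_height, fev1_see, fvc_b0, fvc_b_age, fvc_b_height,
#'   fvc_see` (ratio terms in percent, volumes in liters, height in cm).
#' @return A `copd_reference_equations` tibble.
#' @export
load_reference_equations <- function(path = copd_sys_file("reference_equations_synthetic.csv")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("source", "sex", "group", "age_min", "age_max", "height_min",
              "height_max", "ratio_b0", "ratio_b_age", "ratio_see",
              "fev1_b0", "fev1_b_age", "fev1_b_height", "fev1_see",
              "fvc_b0", "fvc_b_age", "fvc_b_height", "fvc_see")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0L) {
    copd_abort(paste0("reference-equation file missing column(s): ",
                      paste(missing, collapse = ", ")), "copd_equation_error")
  }
  require_provenance(tbl, path)
  if (any(tbl$ratio_see <= 0) || any(tbl$fev1_see <= 0)) {
    copd_abort("SEE columns must be positive (LLN must fall below predicted)",
               "copd_equation_error")
  }
  structure(as_tibble(tbl), class = c("copd_reference_equations", class(as_tibble(tbl))))
}

#' Lower limit of normal for a patient
#'
#' Evaluates the reference equations for the patient's sex, ancestry group,
#' age and height: predicted FEV1/FVC ratio and its LLN (as fractions),
#' predicted FEV1 and FVC (liters) and the FEV1 LLN. This is the
#' demographic-specific threshold that replaces the fixed 0.7 ratio cut and
#' avoids its tendency to overdiagnose obstruction in the elderly.
#'
#' @param patient Named list or one-row tibble with `age` (years), `sex`
#'   (`"male"`/`"female"`), `height` (cm) and `group` (ancestry label; default
#'   `"european"`).
#' @param equations A `copd_reference_equations` table.
#' @return A list: `lln_ratio`, `pred_ratio`, `pred_fev1`, `lln_fev1`,
#'   `pred_fvc`, `source`.
#' @examples
#' eq <- load_reference_equations()
#' compute_lln(list(age = 60, sex = "male", height = 175), eq)$lln_ratio
#' @export
compute_lln <- function(patient, equations = load_reference_equations()) {
  age <- patient[["age"]]
  sex <- patient[["sex"]]
  height <- patient[["height"]]
  group <- patient[["group"]] %||% "european"
  if (!is_scalar_number(age) || !is_scalar_number(height) ||
      length(sex) != 1L || is.na(sex)) {
    copd_abort("compute_lln needs scalar age, sex and height", "copd_equation_error")
  }
  row <- equations[equations$sex == sex & equations$group == group, , drop = FALSE]
  if (nrow(row) == 0L) {
    avail <- unique(equations$group[equations$sex == sex])
    copd_abort(
      paste0("no coefficient row for sex '", sex, "', group '", group,
             "'; available groups: ", paste(avail, collapse = ", ")),
      "copd_group_error"
    )
  }
  row <- row[1, ]
  if (age < row$age_min || age > row$age_max) {
    copd_abort(
      sprintf("age %s outside equation validity range [%s, %s]",
              format(age), row$age_min, row$age_max),
      "copd_range_error"
    )
  }
  if (height < row$height_min || height > row$height_max) {
    copd_abort(
      sprintf("height %s outside equation validity range [%s, %s]",
              format(height), row$height_min, row$height_max),
      "copd_range_error"
    )
  }
  pred_ratio_pct <- row$ratio_b0 + row$ratio_b_age * age
  lln_ratio_pct <- pred_ratio_pct - 1.645 * row$ratio_see
  pred_fev1 <- row$fev1_b0 + row$fev1_b_age * age + row$fev1_b_height * height
  lln_fev1 <- pred_fev1 - 1.645 * row$fev1_see
  pred_fvc <- row$fvc_b0 + row$fvc_b_age * age + row$fvc_b_height * height
  list(
    lln_ratio = lln_ratio_pct / 100,
    pred_ratio = pred_ratio_pct / 100,
    pred_fev1 = pred_fev1,
    lln_fev1 = lln_fev1,
    pred_fvc = pred_fvc,
    source = row$source
  )
}
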