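# Reduction grading: Matta's radiographic criteria, the CT-based 3DCT
# reduction criteria, residual-displacement percentages, overall reduction.

.matta_levels <- c("anatomical", "imperfect", "poor")
.g3_levels <- c("perfect", "good", "moderate")

#' Matta grade of a residual displacement
#'
#' Matta's printed integer bins (anatomical 0-1 mm, imperfect 2-3 mm,
#' poor > 3 mm) are closed continuously at their upper bounds so the grade is
#' defined for every non-negative real: <= 1 mm anatomical, <= 3 mm
#' imperfect, > 3 mm poor.
#'
#' @param residual_mm Residual displacement(s), mm, non-negative.
#' @return Ordered factor with levels anatomical < imperfect < poor.
#' @export
matta_grade <- function(residual_mm) {
  if (any(!is.finite(residual_mm)) || any(residual_mm < 0))
    .stop_invalid("residual displacement must be finite and non-negative")
  factor(ifelse(residual_mm <= 1, "anatomical",
                ifelse(residual_mm <= 3, "imperfect", "poor")),
         levels = .matta_levels, ordered = TRUE)
}

.bin3 <- function(x, lo, hi) {
  factor(ifelse(x <= lo, "perfect", ifelse(x <= hi, "good", "moderate")),
         levels = .g3_levels, ordered = TRUE)
}

#' CT-based 3D reduction grade
#'
#' Per-parameter categories: gap perfect <= 2 mm, good <= 5 mm, moderate
#' > 5 mm; step-off perfect <= 1 mm, good <= 3 mm, moderate > 3 mm; total gap
#' area perfect <= 100 mm^2, good <= 200 mm^2, moderate > 200 mm^2. The final
#' assessment is the category nearest the mean of the ordinal scores
#' (perfect = 1, good = 2, moderate = 3), half-way ties rounded towards the
#' worse grade.
#'
#' @param gap_mm Residual 3D gap, mm.
#' @param step_mm Residual 3D step-off, mm.
#' @param area_mm2 Residual total gap area, mm^2.
#' @return A tibble with rows gap, step_off, total_gap_area and final:
#'   columns `parameter`, `value`, `category`.
#' @export
grade_3dct <- function(gap_mm, step_mm, area_mm2) {
  vals <- c(gap_mm, step_mm, area_mm2)
  if (any(!is.finite(vals)) || any(vals < 0))
    .stop_invalid("residual values must be finite and non-negative")
  cats <- c(as.character(.bin3(gap_mm, 2, 5)),
            as.character(.bin3(step_mm, 1, 3)),
            as.character(.bin3(area_mm2, 100, 200)))
  score <- mean(match(cats, .g3_levels))
  final <- .g3_levels[min(3, floor(score + 0.5 + 1e-12))]
  tibble(parameter = c("gap", "step_off", "total_gap_area", "final"),
         value = c(gap_mm, step_mm, area_mm2, score),
         category = factor(c(cats, final), levels = .g3_levels,
                           ordered = TRUE))
}

#' Residual displacement percentage
#'
#' Postoperative residual as a percentage of the preoperative value:
#' `100 * post / pre`. 0 indicates anatomical reduction; values above 100
#' mean the displacement worsened.
#'
#' @param pre_value Preoperative measurement (> 0).
#' @param post_value Postoperative measurement (>= 0).
#' @return Percentage, or `NA` with a warning when `pre_value` is 0 (the
#'   fracture was already anatomic; the percentage is undefined).
#' @export
residual_pct <- function(pre_value, post_value) {
  if (any(pre_value < 0) || any(post_value < 0))
    .stop_invalid("measurements must be non-negative")
  out <- ifelse(pre_value == 0, NA_real_, 100 * post_value / pre_value)
  if (any(is.na(out)))
    warn("undefined percentage: preoperative value is 0 (already anatomic)")
  out
}

#' Overall reduction percentage
#'
#' Arithmetic mean of the per-parameter residual percentages.
#'
#' @param percentages Numeric vector of residual percentages.
#' @return The mean percentage.
#' @export
overall_reduction <- function(percentages) {
  percentages <- percentages[!is.na(percentages)]
  if (length(percentages) == 0) .stop_invalid("no percentages to average")
  mean(percentages)
}
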