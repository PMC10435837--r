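#' Adjust rate draws for race-ethnicity misclassification
#'
#' Multiplies each draw and stratum by the misclassification ratio of its
#' racial-ethnic group: `m_adjusted = m * c_race`. Applied to model draws
#' before raking, so the subsequent calibration restores county total
#' rates while the adjustment shifts the race-specific composition.
#' Ratios are applied uniformly across ages and years within race
#' (optionally race by sex); the `"Total"` group has ratio 1.
#'
#' @param draws A [draw_cube()] whose strata include a `race` column.
#' @param ratios A [misclass_ratios()] covering every race in the cube.
#' @return The adjusted [draw_cube()].
#' @export
adjust_draws <- function(draws, ratios) {
  if (!"race" %in% names(draws$strata))
    stop("draw cube has no race dimension")
  sx <- if ("sex" %in% names(draws$strata)) draws$strata$sex else NULL
  cvec <- ratio_for(ratios, draws$strata$race, sx)
  draw_cube(draws$strata, draws$draws * cvec)
}
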