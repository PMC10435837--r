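#' Age-standardise rate draws
#'
#' Collapses the age dimension of a draw cube to the weighted sum
#' `ASR = sum_a w_a * m_a` using a fixed standard population's age
#' weights (in the full-scale analysis, the 2010 USA Census structure).
#'
#' @param draws A [draw_cube()] with an `age` dimension.
#' @param standard An [age_standard()] covering every age group present.
#' @return A [draw_cube()] without the age dimension.
#' @export
age_standardise <- function(draws, standard) {
  if (!"age" %in% names(draws$strata))
    stop("draw cube has no age dimension")
  w <- standard$weight[match(draws$strata$age, standard$age)]
  if (anyNA(w))
    stop("age standard missing weight for age group(s): ",
         paste(setdiff(unique(draws$strata$age), standard$age),
               collapse = ", "))
  by <- setdiff(idx_of(draws$strata), "age")
  cc <- cube_cells(draws, by)
  asr <- rowsum(draws$draws * w, cc$id)
  draw_cube(cc$cells[, by, with = FALSE], asr)
}

#' Population-weighted aggregation of rate draws
#'
#' Aggregates age-specific rates over collapsed dimensions as
#' `sum(P * m) / sum(P)` per draw, e.g. both sexes combined or the
#' national level. Aggregation precedes age-standardisation.
#'
#' @param draws A [draw_cube()].
#' @param population Population `count_table`.
#' @param group_by Character vector of index columns to keep (all others
#'   are collapsed).
#' @return A [draw_cube()] over the `group_by` strata.
#' @export
aggregate_weighted <- function(draws, population, group_by) {
  by <- intersect(idx_of(draws$strata), group_by)
  if (!length(by)) stop("group_by must keep at least one index column")
  P <- pop_for_cube(draws, population)
  cc <- cube_cells(draws, by)
  Psum <- rowsum(P, cc$id)
  if (any(Psum == 0))
    stop("all-zero population in an aggregation cell")
  num <- rowsum(draws$draws * P, cc$id)
  draw_cube(cc$cells[, by, with = FALSE], num / drop(Psum))
}

#' Summarise draws into point estimates and uncertainty intervals
#'
#' Point estimate = mean of the draws; 95% uncertainty interval = 2.5th
#' and 97.5th percentiles, computed by linear interpolation between the
#' closest order statistics.
#'
#' @param draws A [draw_cube()] with at least 2 draws.
#' @param scale Reporting scale; rates are multiplied by `1e5` (deaths
#'   per 100,000) by default. Use `scale = 1` for unitless quantities.
#' @param measure Label stored in the `measure` column.
#' @return A summary `data.table`: stratum columns plus `mean`, `lower`,
#'   `upper`, `measure`, `masked` (all `FALSE`; see [apply_masking()]).
#' @export
summarise_draws <- function(draws, scale = 1e5, measure = "rate") {
  if (nrow(draws$strata) == 0L) stop("empty draw cube")
  if (draws$n_draws < 2L) stop("at least 2 draws required to summarise")
  qs <- t(apply(draws$draws, 1L, quantile, probs = c(0.025, 0.975),
                type = 7, names = FALSE))
  out <- copy(draws$strata)
  out[, `:=`(mean = rowMeans(draws$draws) * scale,
             lower = qs[, 1] * scale,
             upper = qs[, 2] * scale,
             measure = measure, masked = FALSE)]
  set_strata_order(out)
  out[]
}

#' Percent change in rates between two draw cubes
#'
#' Computed draw-wise as `100 * (m_t1 - m_t0) / m_t0` and summarised;
#' report declines as positive percent decline by negating.
#'
#' @param draws_t0,draws_t1 [draw_cube()]s on matching strata (the
#'   differing dimension, e.g. `year`, is dropped from the output) with
#'   equal draw counts.
#' @return A summary `data.table` with `measure = "pct_change"`.
#' @export
percent_change <- function(draws_t0, draws_t1) {
  if (draws_t0$n_draws != draws_t1$n_draws)
    stop("draw counts differ")
  by <- intersect(idx_of(draws_t0$strata), idx_of(draws_t1$strata))
  # match on the shared dimensions; the contrasted dimension (disjoint
  # values, e.g. year 2000 vs 2019) is dropped from the output
  match_by <- by[vapply(by, function(cl)
    length(intersect(unique(draws_t0$strata[[cl]]),
                     unique(draws_t1$strata[[cl]]))) > 0L, TRUE)]
  if (!length(match_by)) stop("cubes share no strata to match on")
  m <- cube_align(draws_t0, draws_t1, match_by)
  if (any(draws_t0$draws == 0))
    stop("zero baseline rate; percent change undefined")
  pc <- 100 * (draws_t1$draws[m, , drop = FALSE] - draws_t0$draws) /
    draws_t0$draws
  cube <- list(strata = draws_t0$strata[, match_by, with = FALSE],
               draws = pc, n_draws = ncol(pc))
  class(cube) <- "draw_cube"
  out <- copy(cube$strata)
  qs <- t(apply(pc, 1L, quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE))
  out[, `:=`(mean = rowMeans(pc), lower = qs[, 1], upper = qs[, 2],
             measure = "pct_change", masked = FALSE)]
  set_strata_order(out)
  out[]
}

#' Absolute and relative disparities between two groups
#'
#' Draw-wise difference `m_group - m_reference` (absolute disparity) and
#' ratio `m_group / m_reference` (relative disparity), summarised into
#' point estimates and 95% UIs. A comparison is statistically
#' significant when the posterior probability that the difference
#' exceeds 0 lies outside `(0.025, 0.975)`; draws tied at exactly 0
#' count as not greater.
#'
#' @param draws_group,draws_reference [draw_cube()]s on matching strata
#'   (apart from `race`) with equal draw counts; reference rates must be
#'   strictly positive.
#' @return A summary `data.table` with one `diff` row (deaths per
#'   100,000) and one `ratio` row (unitless) per stratum, both carrying
#'   the same `significant` flag.
#' @export
disparity <- function(draws_group, draws_reference) {
  if (draws_group$n_draws != draws_reference$n_draws)
    stop("draw counts differ")
  by <- setdiff(intersect(idx_of(draws_group$strata),
                          idx_of(draws_reference$strata)), "race")
  m <- cube_align(draws_group, draws_reference, by)
  ref <- draws_reference$draws[m, , drop = FALSE]
  if (any(ref <= 0))
    stop("reference rates must be strictly positive for the ratio")
  dif <- draws_group$draws - ref
  rat <- draws_group$draws / ref
  # strict inequalities: draws tied at exactly 0 support neither side,
  # so identical surfaces are never flagged significant
  p_gt <- rowMeans(dif > 0)
  p_lt <- rowMeans(dif < 0)
  sig <- p_gt >= 0.975 | p_lt >= 0.975
  base <- copy(draws_group$strata)
  qs_d <- t(apply(dif, 1L, quantile, probs = c(0.025, 0.975), type = 7,
                  names = FALSE))
  qs_r <- t(apply(rat, 1L, quantile, probs = c(0.025, 0.975), type = 7,
                  names = FALSE))
  out_d <- copy(base)[, `:=`(mean = rowMeans(dif) * 1e5,
                             lower = qs_d[, 1] * 1e5,
                             upper = qs_d[, 2] * 1e5,
                             measure = "diff", significant = sig,
                             masked = FALSE)]
  out_r <- copy(base)[, `:=`(mean = rowMeans(rat), lower = qs_r[, 1],
                             upper = qs_r[, 2], measure = "ratio",
                             significant = sig, masked = FALSE)]
  out <- rbind(out_d, out_r)
  set_strata_order(out)
  out[]
}

#' Mask estimates for small populations
#'
#' Blanks summary rows for county and racial-ethnic group combinations
#' whose mean annual population (over years, summing sexes and ages) is
#' strictly below `threshold` persons, in every year.
#'
#' @param summary A summary `data.table` with `county` and `race`
#'   columns.
#' @param population Population `count_table` covering the summarised
#'   county-race cells.
#' @param threshold Persons; strictly-less-than comparison (default
#'   1000).
#' @param races Races whose population must all clear the threshold for
#'   a row to stay unmasked; defaults to the row's own race. For
#'   disparity tables pass `c(group, reference)` so a comparison is
#'   masked when either group is masked.
#' @return The summary table with `masked` set and masked rows blanked.
#' @export
apply_masking <- function(summary, population, threshold = 1000,
                          races = NULL) {
  out <- copy(as.data.table(summary))
  if (!all(c("county", "race") %in% names(out)))
    stop("summary must have county and race columns")
  pop <- as.data.table(population)
  mp <- pop[, .(value = sum(value)), by = .(county, race, year)][
    , .(mean_pop = mean(value)), by = .(county, race)]
  is_masked <- function(county_, race_) {
    v <- mp[.(county_, race_), on = c("county", "race")]$mean_pop
    if (anyNA(v))
      stop("population missing for county/race cell(s): ",
           paste(unique(county_[is.na(v)]), collapse = ", "))
    v < threshold
  }
  if (is.null(races)) {
    out[, masked := is_masked(county, race)]
  } else {
    mk <- rep(FALSE, nrow(out))
    for (r in races)
      mk <- mk | is_masked(out$county, rep(r, nrow(out)))
    out[, masked := mk]
  }
  for (col in intersect(c("mean", "lower", "upper"), names(out)))
    out[masked == TRUE, (col) := NA_real_]
  if ("significant" %in% names(out))
    out[masked == TRUE, significant := NA]
  out[]
}

#' County disparity census
#'
#' Among counties with unmasked estimates for both compared groups:
#' how many have a higher point rate in the group than the reference
#' (ratio > 1), and how many of those are statistically significant,
#' with percentages of the unmasked total rounded to one decimal.
#'
#' @param disparities A disparity summary (one `ratio` row per county,
#'   see [disparity()]) with `masked` and `significant` columns.
#' @return A list: `n_total`, `n_higher`, `n_significant`, `pct_higher`,
#'   `pct_significant`.
#' @export
disparity_census <- function(disparities) {
  dt <- as.data.table(disparities)
  if ("measure" %in% names(dt)) dt <- dt[measure == "ratio"]
  if ("masked" %in% names(dt)) dt <- dt[masked %in% FALSE]
  dt <- dt[!is.na(mean)]
  n_total <- nrow(dt)
  if (n_total == 0L) stop("no unmasked counties to census")
  n_higher <- sum(dt$mean > 1)
  n_sig <- sum(dt$mean > 1 & dt$significant %in% TRUE)
  list(n_total = n_total, n_higher = n_higher, n_significant = n_sig,
       pct_higher = round(100 * n_higher / n_total, 1),
       pct_significant = round(100 * n_sig / n_total, 1))
}
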