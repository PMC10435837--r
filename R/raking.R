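# internal: integer cell ids grouping cube rows on `by` columns, plus the
# unique cell table in id order
cube_cells <- function(cube, by) {
  key <- cube$strata[, by, with = FALSE]
  id <- frank(key, ties.method = "dense")
  cells <- unique(copy(key)[, cell := id])
  setorder(cells, cell)
  list(id = id, cells = cells)
}

# align a margin cube's rows to the cell table (one row per cell)
margin_rows <- function(margin, cells, by) {
  m <- margin$strata[, by, with = FALSE][, row := .I]
  j <- m[cells, on = by]$row
  if (anyNA(j) || anyDuplicated(j))
    stop("margin cube does not cover the strata grid on: ",
         paste(by, collapse = ", "))
  j
}

#' Rake race-specific rate draws to a total-population margin
#'
#' For each draw, county, sex, age group, year (and cause), all
#' race-specific rates are scaled by the single factor
#' `f = (P_total * m_total) / sum_r(P_r * m_r)`, so that the
#' population-weighted sum of race-specific rates reproduces the
#' total-population rate exactly. Races with zero population contribute
#' nothing to the margin and are scaled along with the rest.
#'
#' @param draws A [draw_cube()] over races.
#' @param target A [draw_cube()] for the total population (race
#'   `"Total"`) on the same grid without the race dimension, with the
#'   same number of draws.
#' @param population Population `count_table`.
#' @return The raked [draw_cube()].
#' @export
rake_race_margin <- function(draws, target, population) {
  if (draws$n_draws != target$n_draws)
    stop("draw counts differ between cube and target")
  by <- setdiff(idx_of(draws$strata), "race")
  P <- pop_for_cube(draws, population)
  counts <- draws$draws * P
  cc <- cube_cells(draws, by)
  denom <- rowsum(counts, cc$id)
  tj <- margin_rows(target, cc$cells, by)
  Pt <- pop_for_cube(target, population)
  tcounts <- target$draws[tj, , drop = FALSE] * Pt[tj]
  f <- tcounts / denom
  bad <- denom == 0 & tcounts > 0
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("race-specific rates sum to zero against a nonzero total in ",
         "cell ", paste(unlist(cc$cells[w[1], by, with = FALSE]),
                        collapse = "/"), ", draw ", w[2])
  }
  f[denom == 0] <- 1
  draw_cube(draws$strata, draws$draws * f[cc$id, , drop = FALSE])
}

#' Rake cause-specific total-population draws to the all-cause margin
#'
#' Within each draw, county, sex, age group and year, the cause-specific
#' rates of the total population are scaled by the common factor
#' `f = m_all_cause / sum_c(m_c)` so causes sum exactly to the all-cause
#' rate.
#'
#' @param draws A [draw_cube()] over causes (single race).
#' @param target The all-cause [draw_cube()] for the same race.
#' @return The raked [draw_cube()].
#' @export
rake_cause_margin <- function(draws, target) {
  if (draws$n_draws != target$n_draws)
    stop("draw counts differ between cube and target")
  by <- setdiff(idx_of(draws$strata), "cause")
  by <- intersect(by, idx_of(target$strata))
  cc <- cube_cells(draws, by)
  denom <- rowsum(draws$draws, cc$id)
  tj <- margin_rows(target, cc$cells, by)
  tg <- target$draws[tj, , drop = FALSE]
  f <- tg / denom
  bad <- denom == 0 & tg > 0
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("cause-specific rates sum to zero against a nonzero all-cause ",
         "rate in cell ",
         paste(unlist(cc$cells[w[1], by, with = FALSE]), collapse = "/"),
         ", draw ", w[2])
  }
  f[denom == 0] <- 1
  draw_cube(draws$strata, draws$draws * f[cc$id, , drop = FALSE])
}

#' Iterative proportional fitting over races and causes
#'
#' Classical IPF on the expected-death-count array `rate * population`,
#' per draw, county, sex, age group and year: rows (races) are scaled to
#' the race margins and columns (causes) to the cause margins
#' alternately until the maximum relative margin error falls below `tol`.
#' Structural zeros are preserved.
#'
#' @param draws A [draw_cube()] over races x causes.
#' @param race_margins A [draw_cube()] of all-cause rates by race (the
#'   row margins, as rates; converted to counts internally).
#' @param cause_margins A [draw_cube()] of cause-specific total-population
#'   rates (the column margins).
#' @param population Population `count_table`.
#' @param tol Relative margin tolerance (default `1e-10`).
#' @param max_iter Maximum IPF sweeps (default 200).
#' @return The calibrated [draw_cube()] over races x causes.
#' @export
ipf_race_cause <- function(draws, race_margins, cause_margins, population,
                           tol = 1e-10, max_iter = 200L) {
  if (tol <= 0) stop("tol must be > 0")
  nd <- draws$n_draws
  if (race_margins$n_draws != nd || cause_margins$n_draws != nd)
    stop("draw counts differ across cubes")
  races <- sort(unique(draws$strata$race))
  causes <- sort(unique(draws$strata$cause))
  R <- length(races); C <- length(causes)
  by <- setdiff(idx_of(draws$strata), c("race", "cause"))

  # canonical row order: race fastest, then cause, then cell
  st <- copy(draws$strata)[, row := .I]
  cc <- cube_cells(draws, by)
  st[, cell := cc$id]
  setorderv(st, c("cell", "cause", "race"))
  ord <- st$row
  ncell <- nrow(cc$cells)
  if (nrow(st) != R * C * ncell)
    stop("draws cube is not a complete races x causes grid")
  P <- pop_for_cube(draws, population)
  A <- array(draws$draws[ord, , drop = FALSE] * P[ord],
             dim = c(R, C, ncell, nd))

  # margins as counts
  rm_st <- copy(race_margins$strata)[, row := .I]
  rm_st[, cell := cube_cells(race_margins, by)$id]
  setorderv(rm_st, c("cell", "race"))
  if (nrow(rm_st) != R * ncell)
    stop("race margins do not cover the races x cells grid")
  Pm <- pop_for_cube(race_margins, population)
  RM <- array(race_margins$draws[rm_st$row, , drop = FALSE] *
                Pm[rm_st$row], dim = c(R, ncell, nd))

  cm_st <- copy(cause_margins$strata)[, row := .I]
  cm_st[, cell := cube_cells(cause_margins, by)$id]
  setorderv(cm_st, c("cell", "cause"))
  if (nrow(cm_st) != C * ncell)
    stop("cause margins do not cover the causes x cells grid")
  Pc <- pop_for_cube(cause_margins, population)
  CM <- array(cause_margins$draws[cm_st$row, , drop = FALSE] *
                Pc[cm_st$row], dim = c(C, ncell, nd))

  # margin consistency: both must sum to the same cell totals
  tot_r <- colSums(RM)                       # ncell x nd
  tot_c <- colSums(CM)
  rel <- abs(tot_r - tot_c) / pmax(tot_r, tot_c, 1e-300)
  if (max(rel) > sqrt(tol))
    stop("inconsistent margins: race and cause margins disagree on cell ",
         "totals (max relative discrepancy ",
         format(max(rel), digits = 4), ")")

  scale_dim <- function(A, M, dim_races) {
    # dim_races TRUE: match race margins (sum over causes)
    S <- if (dim_races) colSums(aperm(A, c(2, 1, 3, 4))) else colSums(A)
    bad <- S == 0 & M > 0
    if (any(bad))
      stop("IPF margin positive where all current cells are zero; ",
           "structural zeros make the margins unattainable")
    f <- ifelse(S == 0, 1, M / S)
    F4 <- if (dim_races)
      aperm(array(f, c(R, ncell, nd, C)), c(1, 4, 2, 3))
    else
      aperm(array(f, c(C, ncell, nd, R)), c(4, 1, 2, 3))
    A * F4
  }
  resid <- function(A) {
    Sr <- colSums(aperm(A, c(2, 1, 3, 4)))
    Sc <- colSums(A)
    max(abs(Sr - RM) / pmax(RM, 1e-300) * (RM > 0),
        abs(Sc - CM) / pmax(CM, 1e-300) * (CM > 0),
        abs(Sr - RM) * (RM == 0), abs(Sc - CM) * (CM == 0))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- scale_dim(A, RM, TRUE)
    A <- scale_dim(A, CM, FALSE)
    if (resid(A) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("IPF did not converge in ", max_iter, " sweeps (final residual ",
         format(resid(A), digits = 4), ")")

  out <- matrix(A, nrow = R * C * ncell, ncol = nd)
  rates <- out / P[ord]
  rates[P[ord] == 0, ] <- draws$draws[ord, , drop = FALSE][P[ord] == 0, ]
  res <- draws$draws
  res[ord, ] <- rates
  draw_cube(draws$strata, res)
}

#' Two-stage raking of race- and cause-specific draws to county totals
#'
#' Stage 1 rakes the race-specific all-cause draws to the
#' total-population all-cause margin, and the cause-specific
#' total-population draws to the same margin over causes. Stage 2 runs
#' [ipf_race_cause()] on the race-by-cause draws with the stage-1
#' results as margins. After convergence, cause-specific rates sum to
#' each race's all-cause rate, and population-weighted race-specific
#' rates reproduce the total-population rate for every cause, both
#' within `tol`; the county all-cause total is untouched.
#'
#' @param draws_by_race_cause [draw_cube()] over races x modelled causes.
#' @param total_by_cause [draw_cube()] over modelled causes, race
#'   `"Total"`.
#' @param race_all_cause [draw_cube()] over races, cause `"all_cause"`.
#' @param total_all_cause [draw_cube()], race `"Total"`, cause
#'   `"all_cause"`.
#' @param population Population `count_table`.
#' @param tol Relative margin tolerance.
#' @param max_iter Maximum IPF sweeps.
#' @return List with elements `race_cause`, `race_all_cause`,
#'   `total_by_cause`, `total_all_cause` (the first three calibrated,
#'   the last as supplied).
#' @export
rake_two_stage <- function(draws_by_race_cause, total_by_cause,
                           race_all_cause, total_all_cause, population,
                           tol = 1e-10, max_iter = 200L) {
  nd <- draws_by_race_cause$n_draws
  if (!all(c(total_by_cause$n_draws, race_all_cause$n_draws,
             total_all_cause$n_draws) == nd))
    stop("all cubes must share the same number of draws")
  s1_race <- rake_race_margin(race_all_cause, total_all_cause, population)
  s1_cause <- rake_cause_margin(total_by_cause, total_all_cause)
  s2 <- ipf_race_cause(draws_by_race_cause, s1_race, s1_cause,
                       population, tol = tol, max_iter = max_iter)
  list(race_cause = s2, race_all_cause = s1_race,
       total_by_cause = s1_cause, total_all_cause = total_all_cause)
}
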