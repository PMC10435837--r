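#' Declare the strata grid of a scenario or analysis
#'
#' A strata schema fixes the admissible levels of every index dimension:
#' county identifiers, racial-ethnic groups, sexes, ordered age groups,
#' calendar years, and the list of modelled (non-garbage, non-all-cause)
#' causes. All stratified tables are validated against a schema.
#'
#' @param counties Character vector of county identifiers (unique).
#' @param races Character vector of racial-ethnic groups; a subset of
#'   [race_levels()] excluding `"Total"` (the total population is derived by
#'   aggregation, never stored as a stratum of raw data).
#' @param sexes Character vector, subset of [sex_levels()].
#' @param ages Character vector of age-group labels in increasing order.
#'   The full vital-statistics scheme is `0`, `1-4`, then 5-year bands
#'   `5-9` ... `80-84`, `85+`; synthetic scenarios may declare fewer,
#'   coarser groups.
#' @param years Integer vector of consecutive calendar years.
#' @param causes Character vector of modelled causes (e.g.
#'   `c("stomach_cancer", "other")`). Must not contain `"all_cause"` or
#'   `"garbage"`, which are handled as derived / transient labels.
#'
#' @return An object of class `strata_schema`.
#' @export
strata_schema <- function(counties, races, sexes, ages, years, causes) {
  counties <- as.character(counties)
  if (length(counties) < 1L || anyDuplicated(counties))
    stop("counties must be a non-empty vector of unique identifiers")
  races <- as.character(races)
  bad <- setdiff(races, setdiff(race_levels(), RACE_TOTAL))
  if (length(bad))
    stop("unknown race label(s): ", paste(bad, collapse = ", "))
  sexes <- as.character(sexes)
  bad <- setdiff(sexes, sex_levels())
  if (length(bad))
    stop("unknown sex label(s): ", paste(bad, collapse = ", "))
  ages <- as.character(ages)
  if (anyDuplicated(ages)) stop("age groups must be unique")
  years <- as.integer(years)
  if (length(years) && !all(diff(years) == 1L))
    stop("years must be consecutive")
  causes <- as.character(causes)
  if (any(causes %in% c(CAUSE_ALL, CAUSE_GARBAGE)))
    stop("causes must not include 'all_cause' or 'garbage'")
  structure(
    list(counties = counties, races = races, sexes = sexes, ages = ages,
         years = years, causes = causes),
    class = "strata_schema")
}

#' Full vital-statistics age-group scheme
#'
#' The standard tabulation scheme for US death registration data: under
#' 1 year, 1-4 years, then 5-year bands from 5-9 to 80-84, and 85+.
#' Synthetic scenarios typically declare fewer, coarser groups.
#'
#' @return Ordered character vector of 19 age-group labels.
#' @export
vital_age_groups <- function() {
  c("0", "1-4",
    paste(seq(5, 80, by = 5), seq(9, 84, by = 5), sep = "-"),
    "85+")
}

#' @export
print.strata_schema <- function(x, ...) {
  cat("strata_schema:",
      length(x$counties), "counties x", length(x$races), "races x",
      length(x$sexes), "sexes x", length(x$ages), "age groups x",
      length(x$years), "years;",
      length(x$causes), "causes (", paste(x$causes, collapse = ", "), ")\n")
  invisible(x)
}

# full grid as a data.table; `causes` may add transient labels like garbage
schema_grid <- function(schema, with_cause = TRUE, causes = schema$causes) {
  if (with_cause) {
    CJ(county = schema$counties, race = schema$races, sex = schema$sexes,
       age = schema$ages, year = schema$years, cause = causes, sorted = TRUE)
  } else {
    CJ(county = schema$counties, race = schema$races, sex = schema$sexes,
       age = schema$ages, year = schema$years, sorted = TRUE)
  }
}

#' Validate (and grid-complete) a stratified count table
#'
#' Checks a table of death or population counts against a schema: no
#' duplicated strata, all values non-negative and finite, death counts
#' integer. For deaths, missing grid cells are completed with explicit
#' zeros; for population, every modelled cell must be present.
#'
#' @param x A data.frame with the index columns `county`, `race`, `sex`,
#'   `age`, `year` (deaths additionally `cause`) and a `value` column.
#' @param schema A [strata_schema()].
#' @param kind `"deaths"` or `"population"`. Deaths are indexed by cause
#'   and must be integer-valued unless `allow_fractional = TRUE` (counts
#'   that have passed through garbage-code redistribution are real-valued).
#' @param allow_fractional Permit non-integer death counts.
#' @param complete For deaths, complete the grid with explicit zero cells
#'   (default `TRUE`).
#'
#' @return A keyed `data.table` in canonical stratum order with attributes
#'   `schema` and `kind`.
#' @export
count_table <- function(x, schema, kind = c("deaths", "population"),
                        allow_fractional = FALSE, complete = TRUE) {
  kind <- match.arg(kind)
  dt <- as.data.table(x)
  need <- if (kind == "deaths") c(IDX_COLS, "value") else
    c(setdiff(IDX_COLS, "cause"), "value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(kind, " table is missing column(s): ", paste(miss, collapse = ", "))
  dt <- dt[, ..need]
  dt[, year := as.integer(year)]

  check_levels <- function(col, levels) {
    bad <- setdiff(unique(dt[[col]]), levels)
    if (length(bad))
      stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  check_levels("county", schema$counties)
  check_levels("race", schema$races)
  check_levels("sex", schema$sexes)
  check_levels("age", schema$ages)
  check_levels("year", schema$years)
  if (kind == "deaths")
    check_levels("cause", c(schema$causes, CAUSE_GARBAGE, CAUSE_ALL))

  idx <- setdiff(need, "value")
  dup <- dt[, .N, by = idx][N > 1L]
  if (nrow(dup))
    stop("duplicated stratum: ",
         paste(unlist(dup[1, ..idx]), collapse = "/"))
  if (anyNA(dt$value) || any(!is.finite(dt$value)))
    stop("non-finite count values")
  if (any(dt$value < 0))
    stop("negative count values")
  if (kind == "deaths" && !allow_fractional &&
      any(abs(dt$value - round(dt$value)) > 1e-9))
    stop("death counts must be integers")

  if (kind == "deaths" && complete) {
    grid <- schema_grid(schema, causes = intersect(
      unique(c(schema$causes, dt$cause)),
      c(schema$causes, CAUSE_GARBAGE, CAUSE_ALL)))
    dt <- dt[grid, on = idx]
    dt[is.na(value), value := 0]
  }
  if (kind == "population") {
    grid <- schema_grid(schema, with_cause = FALSE)
    found <- dt[grid, on = idx, which = TRUE]
    if (anyNA(found) || nrow(dt) < nrow(grid)) {
      missing_row <- grid[!dt, on = idx]
      stop("population missing for stratum: ",
           paste(unlist(missing_row[1]), collapse = "/"))
    }
  }
  setkeyv(dt, idx)
  set_strata_order(dt)
  setattr(dt, "schema", schema)
  setattr(dt, "kind", kind)
  dt[]
}

#' Age-standard weights
#'
#' A standard population age structure used to age-standardise mortality
#' rates (in the full-scale analysis, the 2010 USA Census age structure).
#'
#' @param ages Character vector of age-group labels.
#' @param weights Numeric weights in `[0, 1]`, one per age group, summing
#'   to 1 within `1e-12`.
#' @return A `data.table` with columns `age`, `weight`, class
#'   `age_standard`.
#' @export
age_standard <- function(ages, weights) {
  ages <- as.character(ages)
  if (length(ages) != length(weights))
    stop("one weight per age group required")
  if (anyDuplicated(ages)) stop("duplicated age group")
  if (any(weights < 0 | weights > 1))
    stop("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1 (got ", format(sum(weights), digits = 16), ")")
  out <- data.table(age = ages, weight = as.numeric(weights))
  setattr(out, "class", c("age_standard", class(out)))
  out[]
}

#' Race-ethnicity misclassification ratios
#'
#' The ratio, per racial-ethnic group (optionally per group and sex), of
#' deaths classified to the group by self-report to deaths classified to
#' the group on death certificates. A ratio above 1 means death
#' certificates undercount the group. The ratio for `"Total"` is exactly 1
#' by construction.
#'
#' @param race Character vector of race labels.
#' @param ratio Strictly positive finite ratios, one per race.
#' @param sex Optional sex labels for race-by-sex ratios.
#' @return A `data.table` with columns `race` (optionally `sex`), `ratio`,
#'   class `misclass_ratios`.
#' @export
misclass_ratios <- function(race, ratio, sex = NULL) {
  if (length(race) != length(ratio))
    stop("one ratio per race required")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratios must be strictly positive and finite")
  out <- if (is.null(sex)) data.table(race = as.character(race), ratio = as.numeric(ratio))
         else data.table(race = as.character(race), sex = as.character(sex),
                         ratio = as.numeric(ratio))
  if (anyDuplicated(out[, !"ratio"])) stop("duplicated ratio rows")
  if (any(out$race == RACE_TOTAL & abs(out$ratio - 1) > 0))
    stop("ratio for Total must be exactly 1")
  setattr(out, "class", c("misclass_ratios", class(out)))
  out[]
}

# look up ratio per (race[, sex]); every race must be covered, Total -> 1
ratio_for <- function(ratios, race, sex = NULL) {
  out <- rep(NA_real_, length(race))
  out[race == RACE_TOTAL] <- 1
  if ("sex" %in% names(ratios) && !is.null(sex)) {
    m <- match(paste(race, sex), paste(ratios$race, ratios$sex))
  } else {
    m <- match(race, ratios$race)
  }
  fill <- is.na(out)
  out[fill] <- ratios$ratio[m[fill]]
  if (anyNA(out))
    stop("no misclassification ratio for race: ",
         paste(unique(race[is.na(out)]), collapse = ", "))
  out
}
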