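#' Redistribute garbage-coded deaths to plausible underlying causes
#'
#' Deaths whose underlying cause is a garbage code are reallocated to the
#' non-garbage causes in proportion to the observed cause composition of
#' a local sharing pool. By default a pool comprises the cells sharing
#' county, sex, coarse age bracket and year (aggregated over race and the
#' fine age groups within the bracket). Pools whose non-garbage
#' composition carries no signal fall back hierarchically: first the
#' county is dropped from the pool definition, then race; if no parent
#' pool has signal, the garbage deaths are spread uniformly over causes
#' and a warning is raised. Totals are conserved exactly at every
#' aggregation level containing a pool; outputs may be non-integer.
#'
#' @param deaths A deaths `count_table` possibly containing
#'   `cause = "garbage"` rows.
#' @param weight_scope Character subset of
#'   `c("county", "race", "sex", "age", "year")` defining the sharing
#'   pools. `"age"` pools on a coarse bracket of the ordered age groups
#'   (see `n_age_brackets`) rather than the fine groups.
#' @param n_age_brackets Number of consecutive coarse brackets the age
#'   groups are split into when `"age"` is in scope.
#' @return A real-valued deaths `count_table` with all garbage cells 0
#'   (garbage rows removed).
#' @export
redistribute_garbage <- function(deaths,
                                 weight_scope = c("county", "sex", "age", "year"),
                                 n_age_brackets = 3L) {
  bad <- setdiff(weight_scope, c("county", "race", "sex", "age", "year"))
  if (length(bad))
    stop("invalid weight_scope column(s): ", paste(bad, collapse = ", "))
  schema <- attr(deaths, "schema")
  dt <- copy(as.data.table(deaths))
  dt[, value := as.numeric(value)]
  garbage <- dt[cause == CAUSE_GARBAGE & value > 0]
  body <- dt[cause != CAUSE_GARBAGE]
  if (!nrow(garbage))
    return(count_table(body, schema, kind = "deaths",
                       allow_fractional = TRUE))

  causes <- setdiff(unique(body$cause), CAUSE_ALL)
  # coarse age brackets: consecutive runs of the ordered age groups
  ages <- schema$ages
  br <- ceiling(seq_along(ages) / (length(ages) / n_age_brackets))
  bracket_of <- setNames(paste0("bracket", br), ages)
  body[, age_bracket := bracket_of[age]]
  garbage[, age_bracket := bracket_of[age]]
  scope_cols <- function(scope) {
    sc <- scope
    sc[sc == "age"] <- "age_bracket"
    sc
  }

  # fallback chain: full scope, drop county, drop race, global pool
  chain <- list(weight_scope)
  if ("county" %in% weight_scope)
    chain <- c(chain, list(setdiff(weight_scope, "county")))
  if ("race" %in% weight_scope)
    chain <- c(chain, list(setdiff(chain[[length(chain)]], "race")))
  chain <- c(chain, list(character()))

  n_g <- nrow(garbage)
  wmat <- matrix(NA_real_, n_g, length(causes),
                 dimnames = list(NULL, causes))
  unresolved <- rep(TRUE, n_g)
  for (scope in chain) {
    if (!any(unresolved)) break
    sc <- scope_cols(scope)
    pool <- if (length(sc)) {
      body[cause %in% causes,
           .(w = sum(value)), by = c(sc, "cause")]
    } else {
      body[cause %in% causes, .(w = sum(value)), by = "cause"]
    }
    if (!nrow(pool)) next
    if (length(sc)) {
      wide <- dcast(pool, stats::as.formula(
        paste(paste(sc, collapse = "+"), "~ cause")),
        value.var = "w", fill = 0)
      for (cz in setdiff(causes, names(wide))) wide[, (cz) := 0]
      m <- wide[garbage[unresolved], on = sc]
      pw <- as.matrix(m[, causes, with = FALSE])
      pw[is.na(pw)] <- 0
    } else {
      wv <- setNames(rep(0, length(causes)), causes)
      wv[pool$cause] <- pool$w
      pw <- matrix(wv, nrow = sum(unresolved), ncol = length(causes),
                   byrow = TRUE)
    }
    has_signal <- rowSums(pw) > 0
    if (any(has_signal)) {
      rows <- which(unresolved)[has_signal]
      wmat[rows, ] <- pw[has_signal, , drop = FALSE] /
        rowSums(pw)[has_signal]
      unresolved[rows] <- FALSE
    }
  }
  if (any(unresolved)) {
    warning("no pool with non-garbage deaths for ", sum(unresolved),
            " garbage cell(s); allocating uniformly over causes")
    wmat[unresolved, ] <- 1 / length(causes)
  }

  add <- garbage[rep(seq_len(n_g), each = length(causes))]
  add[, cause := rep(causes, times = n_g)]
  add[, value := as.vector(t(wmat * garbage$value))]
  out <- rbind(body[, c(IDX_COLS, "value"), with = FALSE],
               add[, c(IDX_COLS, "value"), with = FALSE])[
    , .(value = sum(value)), by = IDX_COLS]
  count_table(out, schema, kind = "deaths", allow_fractional = TRUE)
}
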