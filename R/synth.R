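#' Generate a synthetic county geography
#'
#' @param n_counties Number of counties (>= 2).
#' @param layout `"grid"` for rook adjacency on the most-square grid
#'   containing `n_counties` nodes (filled row-major, last row possibly
#'   partial), or `"random_planar"` for a connected random geometric
#'   graph (3-nearest-neighbour edges united with a minimum spanning tree
#'   over random points in the unit square).
#' @param seed Integer seed; the result is a pure function of
#'   `(n_counties, layout, seed)`.
#' @return A [county_graph()].
#' @export
generate_geography <- function(n_counties, layout = c("grid", "random_planar"),
                               seed = 1L) {
  layout <- match.arg(layout)
  n_counties <- as.integer(n_counties)
  if (is.na(n_counties) || n_counties < 2L)
    stop("n_counties must be >= 2")
  ids <- sprintf("c%03d", seq_len(n_counties))
  if (layout == "grid") {
    nr <- floor(sqrt(n_counties))
    nc <- ceiling(n_counties / nr)
    col <- (seq_len(n_counties) - 1L) %% nc
    # rook neighbours: right and down where both cells exist
    right <- which(col < nc - 1L & seq_len(n_counties) < n_counties)
    e1 <- cbind(ids[right], ids[right + 1L])
    down <- which(seq_len(n_counties) + nc <= n_counties)
    e2 <- cbind(ids[down], ids[down + nc])
    county_graph(ids, rbind(e1, e2))
  } else {
    set.seed(seed)
    xy <- cbind(runif(n_counties), runif(n_counties))
    d <- as.matrix(stats::dist(xy))
    k <- min(3L, n_counties - 1L)
    knn <- do.call(rbind, lapply(seq_len(n_counties), function(i) {
      nb <- order(d[i, ])[2:(k + 1L)]
      cbind(ids[i], ids[nb])
    }))
    ig <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE)
    mst <- igraph::mst(ig)
    me <- igraph::as_edgelist(mst, names = FALSE)
    mst_edges <- cbind(ids[me[, 1]], ids[me[, 2]])
    county_graph(ids, rbind(knn, mst_edges))
  }
}

# integer apportionment of total T over weights w by largest remainder;
# sums to T exactly
apportion <- function(total, w) {
  if (total == 0) return(rep(0L, length(w)))
  w <- w / sum(w)
  q <- total * w
  base <- floor(q)
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    bump <- order(q - base, decreasing = TRUE)[seq_len(short)]
    base[bump] <- base[bump] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic stratified population table
#'
#' County totals are drawn log-uniformly in `size_range` and split across
#' races by county-specific Dirichlet shares, across sexes evenly, and
#' across age groups by a declining pyramid; totals drift smoothly over
#' years at county-specific growth rates. Integer apportionment (largest
#' remainder) makes strata sum exactly to the drawn county-year totals.
#'
#' @param graph A [county_graph()].
#' @param schema A [strata_schema()]; its counties must match the graph.
#' @param size_range Numeric `[min, max]` county population in persons.
#' @param seed Integer seed.
#' @param growth_range Range of the annual county growth rate.
#' @param race_alpha Dirichlet concentration per race (named or in schema
#'   race order); larger values give more even shares. Default: 12 for
#'   White (majority share), 4 otherwise.
#' @param age_decay Geometric decline rate of the age pyramid across the
#'   ordered age groups.
#' @param absent_races Character vector of races with population 0 (and
#'   hence no deaths) everywhere; supports masking tests.
#' @return A population `count_table` (strata all positive unless a race
#'   is absent).
#' @export
generate_population <- function(graph, schema, size_range = c(1e3, 1e5),
                                seed = 1L, growth_range = c(-0.01, 0.02),
                                race_alpha = NULL, age_decay = 0.35,
                                absent_races = character()) {
  if (size_range[1] < 0) stop("size_range minimum must be >= 0")
  if (size_range[1] > size_range[2]) stop("size_range must be [min, max] with min <= max")
  stopifnot(setequal(graph$counties, schema$counties))
  set.seed(seed)
  nj <- length(schema$counties)
  nr <- length(schema$races)
  na <- length(schema$ages)
  ns <- length(schema$sexes)
  base <- exp(runif(nj, log(size_range[1]), log(size_range[2])))
  growth <- runif(nj, growth_range[1], growth_range[2])

  if (is.null(race_alpha)) {
    race_alpha <- ifelse(schema$races == "White", 12, 4)
    names(race_alpha) <- schema$races
  }
  if (!is.null(names(race_alpha)))
    race_alpha <- race_alpha[schema$races]
  shares_race <- matrix(0, nj, nr)
  for (j in seq_len(nj)) {
    g <- rgamma(nr, shape = race_alpha)
    shares_race[j, ] <- g / sum(g)
  }
  shares_race[, schema$races %in% absent_races] <- 0
  if (any(rowSums(shares_race) == 0)) stop("no race left with population")
  shares_race <- shares_race / rowSums(shares_race)

  shares_age <- exp(-age_decay * (seq_len(na) - 1L))
  shares_age <- shares_age / sum(shares_age)
  w_cell <- as.vector(outer(shares_age, rep(1 / ns, ns)))  # age fastest
  cell_grid <- data.table(sex = rep(schema$sexes, each = na),
                          age = rep(schema$ages, times = ns))
  out <- vector("list", nj * length(schema$years))
  k <- 0L
  for (j in seq_len(nj)) {
    for (ti in seq_along(schema$years)) {
      total_jt <- max(1L, round(base[j] * (1 + growth[j])^(ti - 1L)))
      by_race <- apportion(total_jt, shares_race[j, ])
      for (r in seq_len(nr)) {
        if (shares_race[j, r] == 0) {
          vals <- rep(0L, nrow(cell_grid))
        } else {
          vals <- apportion(by_race[r], w_cell)
          # keep modelled strata positive without changing the total
          while (any(vals == 0L)) {
            z <- which(vals == 0L)
            big <- which.max(vals)
            take <- min(length(z), vals[big] - 1L)
            if (take <= 0L) break
            vals[z[seq_len(take)]] <- 1L
            vals[big] <- vals[big] - take
          }
        }
        k <- k + 1L
        out[[k]] <- data.table(county = schema$counties[j],
                               race = schema$races[r],
                               sex = cell_grid$sex, age = cell_grid$age,
                               year = schema$years[ti], value = vals)
      }
    }
  }
  count_table(rbindlist(out), schema, kind = "population")
}

#' Generate county-level covariates
#'
#' Independent standard-normal county covariates (e.g. a deprivation
#' index); enough for exercising the covariate pathway of the model.
#'
#' @param graph A [county_graph()].
#' @param names Character vector of covariate names.
#' @param seed Integer seed.
#' @return A `data.table` with column `county` plus one column per
#'   covariate.
#' @export
generate_covariates <- function(graph, names = "dep_index", seed = 1L) {
  set.seed(seed)
  out <- data.table(county = graph$counties)
  for (nm in names) out[, (nm) := rnorm(length(graph$counties))]
  out[]
}

# draw x ~ N(0, (tau * Qt)^-1) in basis coordinates and map back: A %*% x
sample_structured_effect <- function(Q, A, tau) {
  Qt <- as.matrix(Matrix::crossprod(A, Q %*% A))
  if (!nrow(Qt)) return(rep(0, nrow(A)))
  R <- chol(tau * Qt)
  as.vector(A %*% backsolve(R, rnorm(ncol(A))))
}

#' Generate a true mortality-rate surface with known parameters
#'
#' Draws truth from the same model family the estimator assumes:
#' `log m = beta0_race + X gamma + u_county + v_age + w_year`, with `u`
#' ICAR over the adjacency graph, `v` and `w` first-order random walks,
#' all sum-to-zero. One surface per modelled cause; the all-cause surface
#' is the sum of cause-specific rates. An optional unmodelled
#' county-by-race shock (`misspec_shock_sd > 0`) supports
#' misspecification probes.
#'
#' @param graph A [county_graph()].
#' @param schema A [strata_schema()].
#' @param params Named list, one entry per cause in `schema$causes`, each
#'   a list with `beta0` (named log-rate intercept per race), `gamma`
#'   (named covariate effects, optional), and precisions `tau_u`,
#'   `tau_v`, `tau_w` (> 0).
#' @param covariates Optional county covariate table (see
#'   [generate_covariates()]); covariates are centred and scaled before
#'   applying `gamma`.
#' @param seed Integer seed.
#' @param misspec_shock_sd Standard deviation of an optional iid
#'   county-by-race log-rate shock outside the estimator's model family.
#' @return A `scenario_truth` object: list with `rates` (stratified table
#'   of true rates per person-year, including `all_cause`), `params`, and
#'   the realised random effects.
#' @export
generate_true_rates <- function(graph, schema, params, covariates = NULL,
                                seed = 1L, misspec_shock_sd = 0) {
  stopifnot(setequal(names(params), schema$causes))
  for (p in params) {
    if (any(!is.finite(unlist(p[c("beta0", "tau_u", "tau_v", "tau_w")]))))
      stop("non-finite generative parameter")
    if (any(unlist(p[c("tau_u", "tau_v", "tau_w")]) <= 0))
      stop("precisions must be strictly positive")
  }
  set.seed(seed)
  nj <- length(schema$counties); na <- length(schema$ages)
  nt <- length(schema$years); nr <- length(schema$races)
  Q_u <- icar_structure(graph)
  A_u <- component_basis(graph_components(graph))
  Q_a <- rw1_structure(na); A_a <- sum_to_zero_basis(na)
  Q_t <- rw1_structure(nt); A_t <- sum_to_zero_basis(nt)

  xg <- rep(0, nj)
  grid <- schema_grid(schema)
  effects <- list()
  rate_tabs <- vector("list", length(schema$causes))
  for (ci in seq_along(schema$causes)) {
    cz <- schema$causes[ci]
    p <- params[[cz]]
    u <- sample_structured_effect(Q_u, A_u, p$tau_u)
    v <- sample_structured_effect(Q_a, A_a, p$tau_v)
    w <- sample_structured_effect(Q_t, A_t, p$tau_w)
    if (!is.null(p$gamma) && !is.null(covariates)) {
      X <- scale(as.matrix(covariates[match(schema$counties, covariates$county),
                                      names(p$gamma), with = FALSE]))
      X[is.nan(X)] <- 0
      xg <- as.vector(X %*% p$gamma)
    } else xg <- rep(0, nj)
    z <- if (misspec_shock_sd > 0)
      matrix(rnorm(nj * nr, sd = misspec_shock_sd), nj, nr,
             dimnames = list(schema$counties, schema$races))
    else matrix(0, nj, nr, dimnames = list(schema$counties, schema$races))

    sub <- grid[cause == cz]
    jj <- match(sub$county, schema$counties)
    logm <- p$beta0[sub$race] + xg[jj] + u[jj] +
      v[match(sub$age, schema$ages)] + w[match(sub$year, schema$years)] +
      z[cbind(jj, match(sub$race, schema$races))]
    rate_tabs[[ci]] <- sub[, .(county, race, sex, age, year, cause,
                               rate = exp(logm))]
    effects[[cz]] <- list(u = setNames(u, schema$counties),
                          v = setNames(v, schema$ages),
                          w = setNames(w, as.character(schema$years)),
                          xg = setNames(xg, schema$counties), z = z)
  }
  rates <- rbindlist(rate_tabs)
  allc <- rates[, .(cause = CAUSE_ALL, rate = sum(rate)),
                by = c("county", "race", "sex", "age", "year")]
  rates <- rbind(rates, allc[, names(rates), with = FALSE])
  set_strata_order(rates)
  if (any(!is.finite(rates$rate)) || any(rates$rate <= 0))
    stop("true rates must be positive and finite")
  structure(list(rates = rates[], params = params, effects = effects,
                 schema = schema),
            class = "scenario_truth")
}

#' Sample Poisson death counts from a true rate surface
#'
#' `deaths ~ Poisson(P * m)` independently per stratum and cause (the
#' derived all-cause surface is not sampled).
#'
#' @param truth A `scenario_truth` from [generate_true_rates()].
#' @param population A population `count_table` on the same schema.
#' @param seed Integer seed.
#' @return A deaths `count_table` over the modelled causes.
#' @export
sample_deaths <- function(truth, population, seed = 1L) {
  schema <- truth$schema
  rates <- truth$rates[cause != CAUSE_ALL]
  idx <- setdiff(IDX_COLS, "cause")
  dt <- merge(rates, as.data.table(population), by = idx)
  if (nrow(dt) != nrow(rates))
    stop("rate and population tables do not cover the same strata")
  set_strata_order(dt)
  set.seed(seed)
  dt[, deaths := rpois(.N, value * rate)]
  out <- dt[, .(county, race, sex, age, year, cause, value = deaths)]
  count_table(out, schema, kind = "deaths")
}

#' Misreport race-ethnicity on synthetic death records
#'
#' Reassigns deaths between race labels within each county, sex, age,
#' year and cause cell so that, in expectation, the ratio of
#' self-reported (input) to certificate (output) deaths per race matches
#' the supplied misclassification ratio. Races with ratio > 1 donate a
#' binomial fraction `1 - 1/ratio` of their deaths; donations flow
#' multinomially to races with ratio < 1 in proportion to their expected
#' deficit. Totals per cell are conserved exactly.
#'
#' @param deaths A deaths `count_table` indexed by true (self-reported)
#'   race.
#' @param ratios A [misclass_ratios()] covering every race present.
#' @param seed Integer seed.
#' @return A deaths `count_table` indexed by certificate race.
#' @export
apply_misreporting <- function(deaths, ratios, seed = 1L) {
  schema <- attr(deaths, "schema")
  dt <- copy(as.data.table(deaths))
  races <- sort(unique(dt$race))
  cvec <- ratio_for(ratios, races)
  donors <- races[cvec > 1]
  receivers <- races[cvec < 1]
  if (length(donors) && !length(receivers))
    stop("infeasible misclassification ratios (no race can receive ",
         "misreported deaths): ",
         paste(sprintf("%s=%.4g", races, cvec), collapse = ", "))
  if (!length(donors)) {
    if (length(receivers))
      stop("infeasible misclassification ratios (no race can donate ",
           "misreported deaths): ",
           paste(sprintf("%s=%.4g", races, cvec), collapse = ", "))
    return(count_table(dt, schema, kind = "deaths"))
  }

  set.seed(seed)
  cells <- c("county", "sex", "age", "year", "cause")
  dt[, value := as.numeric(value)]
  dt[, cell := .GRP, by = cells]
  cmap <- setNames(cvec, races)
  dt[, moved := 0]
  dt[race %in% donors,
     moved := as.numeric(rbinom(.N, as.integer(value), 1 - 1 / cmap[race]))]
  wide <- dcast(dt, cell ~ race, value.var = c("value", "moved"), fill = 0)
  recv_w <- function(vals) {
    # deficit weights: cell deaths * (1/c - 1); fall back to ratio deficit
    w <- vals * (1 / cmap[receivers] - 1)
    if (sum(w) == 0) w <- (1 / cmap[receivers] - 1)
    w / sum(w)
  }
  val_cols <- paste0("value_", receivers)
  mv_cols <- paste0("moved_", donors)
  recv_mat <- as.matrix(wide[, ..val_cols])
  out_mat <- recv_mat
  total_moved <- rowSums(as.matrix(wide[, ..mv_cols]))
  for (i in which(total_moved > 0)) {
    pr <- recv_w(recv_mat[i, ])
    add <- if (length(receivers) == 1L) total_moved[i] else
      as.vector(rmultinom(1L, total_moved[i], pr))
    out_mat[i, ] <- recv_mat[i, ] + add
  }
  for (ri in seq_along(receivers))
    wide[, (val_cols[ri]) := out_mat[, ri]]
  for (dn in donors)
    wide[, (paste0("value_", dn)) :=
           get(paste0("value_", dn)) - get(paste0("moved_", dn))]
  long <- melt(wide, id.vars = "cell",
               measure.vars = paste0("value_", races),
               variable.name = "race", value.name = "value")
  long[, race := sub("^value_", "", race)]
  key <- unique(dt[, c("cell", cells), with = FALSE])
  out <- long[key, on = "cell"][, c(IDX_COLS, "value"), with = FALSE]
  count_table(out, schema, kind = "deaths")
}

#' Relabel a fraction of deaths as garbage-coded
#'
#' Each non-garbage death is independently assigned the garbage cause
#' with probability `g` (optionally race-specific), emulating
#' insufficiently specific underlying-cause coding. Cell totals are
#' conserved: relabelled deaths reappear as `cause = "garbage"` in the
#' same county, race, sex, age and year.
#'
#' @param deaths A deaths `count_table`.
#' @param g Garbage probability in `[0, 1)`; scalar or named per race.
#' @param seed Integer seed.
#' @return A deaths `count_table` including a garbage cause.
#' @export
inject_garbage_codes <- function(deaths, g, seed = 1L) {
  if (any(g < 0) || any(g >= 1)) stop("garbage fraction must lie in [0, 1)")
  schema <- attr(deaths, "schema")
  dt <- copy(as.data.table(deaths))
  if (all(g == 0)) return(count_table(dt, schema, kind = "deaths"))
  set.seed(seed)
  gr <- if (is.null(names(g))) rep(g[1], nrow(dt)) else {
    if (!all(unique(dt$race) %in% names(g)))
      stop("race-specific g must name every race")
    unname(g[dt$race])
  }
  nong <- dt$cause != CAUSE_GARBAGE
  moved <- integer(nrow(dt))
  moved[nong] <- rbinom(sum(nong), as.integer(dt$value[nong]), gr[nong])
  dt[, value := value - moved]
  gtab <- dt[, .(county, race, sex, age, year, moved)][
    , .(value = sum(moved)), by = c("county", "race", "sex", "age", "year")]
  gtab[, cause := CAUSE_GARBAGE]
  prior_garbage <- as.data.table(deaths)[cause == CAUSE_GARBAGE]
  if (nrow(prior_garbage))
    gtab <- rbind(gtab, prior_garbage[, .(county, race, sex, age, year,
                                          value, cause)])[
      , .(value = sum(value)), by = c("county", "race", "sex", "age",
                                      "year", "cause")]
  out <- rbind(dt[cause != CAUSE_GARBAGE, c(IDX_COLS, "value"), with = FALSE],
               gtab[, c(IDX_COLS, "value"), with = FALSE])
  count_table(out, schema, kind = "deaths")
}
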