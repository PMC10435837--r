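#' Default synthetic scenario configuration
#'
#' The reference desk-scale scenario: 36 counties on a 6x6 rook grid,
#' two racial-ethnic groups plus the derived total, one sex, five age
#' groups, ten years, two modelled causes (stomach cancer and a large
#' residual "other" cause) whose sum is the all-cause surface. Truth is
#' drawn from the estimator's own model family (well-specified); the
#' observation process adds race misreporting on death certificates and
#' a ~27% garbage-coded fraction, both switchable.
#'
#' @return A named list of configuration entries; override entries via
#'   [read_config()] or [utils::modifyList()].
#' @export
default_scenario_config <- function() {
  list(
    n_counties = 36L,
    layout = "grid",
    races = c("Black", "White"),
    sexes = "both",
    ages = c("0-24", "25-44", "45-64", "65-84", "85+"),
    years = 2010:2019,
    causes = c("stomach_cancer", "other"),
    size_range = c(1e3, 1e5),
    growth_range = c(-0.01, 0.02),
    race_alpha = c(Black = 4, White = 12),
    age_decay = 0.35,
    covariate_names = "dep_index",
    params = list(
      stomach_cancer = list(
        beta0 = c(Black = log(7e-5), White = log(4e-5)),
        gamma = c(dep_index = 0.15),
        tau_u = 25, tau_v = 2, tau_w = 100),
      other = list(
        beta0 = c(Black = log(9.5e-3), White = log(8.5e-3)),
        gamma = c(dep_index = 0.10),
        tau_u = 25, tau_v = 2, tau_w = 100)),
    age_standard_weights = c(0.33, 0.27, 0.24, 0.13, 0.03),
    misclass = list(race = c("Black", "White"), ratio = c(1.05, 0.98)),
    garbage_fraction = 0.27,
    misspec_shock_sd = 0,
    n_draws = 1000L,
    redistribute_scope = c("county", "sex", "age", "year"),
    n_age_brackets = 3L,
    masking_threshold = 1000,
    reference_race = "White",
    rake_tol = 1e-10,
    rake_max_iter = 200L,
    fit_tol = 1e-6,
    fit_max_iter = 2000L,
    hyper_sd = 3,
    seed = 20231L
  )
}

scenario_schema <- function(config) {
  counties <- sprintf("c%03d", seq_len(config$n_counties))
  strata_schema(counties, config$races, config$sexes, config$ages,
                as.integer(config$years), config$causes)
}

scenario_age_standard <- function(config) {
  age_standard(config$ages, config$age_standard_weights)
}

scenario_ratios <- function(config) {
  misclass_ratios(config$misclass$race, config$misclass$ratio,
                  config$misclass$sex)
}

# one root seed deterministically spawns per-stage seeds
spawn_seeds <- function(seed, stages) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Simulate a complete synthetic scenario with known truth
#'
#' Runs the full generative chain: geography, population, covariates,
#' true rate surfaces, Poisson deaths, race misreporting on the death
#' certificate, and garbage-code injection.
#'
#' @param config A configuration list (see [default_scenario_config()]).
#' @param seed Root seed; per-stage seeds are spawned deterministically
#'   from it. Defaults to `config$seed`.
#' @return A list: `graph`, `schema`, `population`, `covariates`,
#'   `truth`, `deaths_true` (by self-reported race, fully cause-coded),
#'   `deaths_observed` (certificate race, garbage-coded), `ratios`,
#'   `standard`, `config`, `seeds`.
#' @export
simulate_scenario <- function(config = default_scenario_config(),
                              seed = config$seed) {
  seeds <- spawn_seeds(seed, c("geography", "population", "covariates",
                               "truth", "deaths", "misreport", "garbage",
                               "draws"))
  schema <- scenario_schema(config)
  graph <- generate_geography(config$n_counties, config$layout,
                              seed = seeds[["geography"]])
  population <- generate_population(
    graph, schema, size_range = config$size_range,
    seed = seeds[["population"]], growth_range = config$growth_range,
    race_alpha = config$race_alpha, age_decay = config$age_decay,
    absent_races = config$absent_races %||% character())
  covariates <- generate_covariates(graph, config$covariate_names,
                                    seed = seeds[["covariates"]])
  truth <- generate_true_rates(graph, schema, config$params, covariates,
                               seed = seeds[["truth"]],
                               misspec_shock_sd = config$misspec_shock_sd)
  deaths_true <- sample_deaths(truth, population, seed = seeds[["deaths"]])
  ratios <- scenario_ratios(config)
  deaths_cert <- apply_misreporting(deaths_true, ratios,
                                    seed = seeds[["misreport"]])
  deaths_observed <- inject_garbage_codes(deaths_cert,
                                          config$garbage_fraction,
                                          seed = seeds[["garbage"]])
  list(graph = graph, schema = schema, population = population,
       covariates = covariates, truth = truth, deaths_true = deaths_true,
       deaths_cert = deaths_cert, deaths_observed = deaths_observed,
       ratios = ratios, standard = scenario_age_standard(config),
       config = config, seeds = seeds)
}

# derived all-cause rows appended to a deaths table
with_all_cause <- function(deaths) {
  dt <- as.data.table(deaths)[cause != CAUSE_ALL]
  allc <- dt[, .(value = sum(value), cause = CAUSE_ALL),
             by = .(county, race, sex, age, year)]
  out <- rbind(dt, allc[, names(dt), with = FALSE])
  count_table(out, attr(deaths, "schema"), kind = "deaths",
              allow_fractional = TRUE)
}

#' Fit all models and draw posterior rate surfaces for one sex
#'
#' Fits the race-stratified model and the total-population model for
#' every modelled cause and for the all-cause surface, then simulates
#' posterior draws from each fit. Draw seeds are spawned from `seed` per
#' model.
#'
#' @param deaths Redistributed deaths `count_table` (no garbage rows).
#' @param population Population `count_table`.
#' @param covariates County covariate table or `NULL`.
#' @param graph A [county_graph()].
#' @param schema A [strata_schema()].
#' @param sex Sex to fit.
#' @param n_draws Draws per model.
#' @param seed Root seed for the draw stage.
#' @param tol,max_iter,hyper_sd Passed to [build_inputs()] / [fit_map()].
#' @return A list with `fits` and `cubes`, each keyed
#'   `<cause>.<race_set>` where race_set is `races` or `Total`.
#' @export
fit_all_models <- function(deaths, population, covariates, graph, schema,
                           sex, n_draws = 1000L, seed = 1L, tol = 1e-6,
                           max_iter = 2000L, hyper_sd = 3) {
  deaths <- with_all_cause(deaths)
  causes <- c(schema$causes, CAUSE_ALL)
  specs <- CJ(cause = causes, race_set = c("races", "Total"))
  keys <- paste(specs$cause, specs$race_set, sep = ".")
  seeds <- spawn_seeds(seed, keys)
  fits <- list(); cubes <- list()
  for (i in seq_len(nrow(specs))) {
    cz <- specs$cause[i]
    races <- if (specs$race_set[i] == "Total") RACE_TOTAL else schema$races
    key <- keys[i]
    message(sprintf("fitting %s [%s] ...", cz,
                    paste(races, collapse = "+")))
    inputs <- build_inputs(deaths, population, covariates, graph, schema,
                           cause = cz, sex = sex, races = races,
                           hyper_sd = hyper_sd)
    fits[[key]] <- fit_map(inputs, tol = tol, max_iter = max_iter)
    cubes[[key]] <- draw_posterior(fits[[key]], n_draws = n_draws,
                                   seed = seeds[[key]])
  }
  list(fits = fits, cubes = cubes)
}

#' Run the full estimation pipeline on a synthetic scenario
#'
#' Executes, per sex: simulate -> redistribute garbage codes -> fit the
#' small-area models and draw posterior rate surfaces -> adjust
#' race-specific draws for misclassification -> two-stage raking to
#' county totals -> summarise age-standardised rates, disparities
#' against the reference race, masking, and the county disparity
#' census. All outputs are written as delimited text to `output_dir`
#' together with a manifest of seeds and stage timings; re-running with
#' the same config and seed reproduces the outputs exactly.
#'
#' @param config Configuration list or path to a YAML config file.
#' @param seed Root seed (defaults to `config$seed`).
#' @param output_dir Output directory (created if needed); `NULL` skips
#'   file output.
#' @return (Invisibly) a list with the scenario, cubes, summary tables
#'   and census records.
#' @export
run_pipeline <- function(config = default_scenario_config(),
                         seed = NULL, output_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  seed <- seed %||% config$seed
  t_all <- proc.time()[3]
  stage <- function(name) message(sprintf("[%s] stage: %s",
                                          format(Sys.time(), "%H:%M:%S"),
                                          name))
  stage("simulate")
  scn <- simulate_scenario(config, seed = seed)
  stage("redistribute")
  deaths_rd <- redistribute_garbage(scn$deaths_observed,
                                    weight_scope = config$redistribute_scope,
                                    n_age_brackets = config$n_age_brackets)
  stage("fit")
  sex <- config$sexes[1]
  fitted <- fit_all_models(deaths_rd, scn$population, scn$covariates,
                           scn$graph, scn$schema, sex = sex,
                           n_draws = config$n_draws,
                           seed = scn$seeds[["draws"]],
                           tol = config$fit_tol,
                           max_iter = config$fit_max_iter,
                           hyper_sd = config$hyper_sd)
  cubes <- fitted$cubes
  stage("adjust")
  adj <- list()
  for (cz in c(scn$schema$causes, CAUSE_ALL)) {
    adj[[cz]] <- adjust_draws(cubes[[paste0(cz, ".races")]], scn$ratios)
  }
  stage("rake")
  race_cause <- do.call(cube_rbind, adj[scn$schema$causes])
  total_cause <- do.call(cube_rbind,
                         cubes[paste0(scn$schema$causes, ".Total")])
  raked <- rake_two_stage(race_cause, total_cause, adj[[CAUSE_ALL]],
                          cubes[[paste0(CAUSE_ALL, ".Total")]],
                          scn$population, tol = config$rake_tol,
                          max_iter = config$rake_max_iter)
  stage("summarise")
  target_cause <- scn$schema$causes[1]
  cube_final <- cube_subset(raked$race_cause, cause = target_cause)
  asr <- age_standardise(cube_final, scn$standard)
  est <- summarise_draws(asr)
  est <- apply_masking(est, scn$population,
                       threshold = config$masking_threshold)
  ref <- config$reference_race
  disp <- list(); census <- list()
  for (r in setdiff(scn$schema$races, ref)) {
    d <- disparity(cube_subset(asr, race = r),
                   cube_subset(asr, race = ref))
    d <- apply_masking(d, scn$population,
                       threshold = config$masking_threshold,
                       races = c(r, ref))
    disp[[r]] <- d
    last_year <- max(scn$schema$years)
    census[[r]] <- disparity_census(d[year == last_year])
  }
  disparities <- rbindlist(disp)
  census_dt <- rbindlist(lapply(names(census), function(r)
    c(list(race = r, reference = ref), census[[r]])))

  result <- list(scenario = scn, deaths_redistributed = deaths_rd,
                 fits = fitted$fits, cubes = cubes, raked = raked,
                 estimates = est, disparities = disparities,
                 census = census_dt)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(output_dir, f)
    write_count_table(scn$population, out("population.csv"))
    write_count_table(scn$deaths_observed, out("deaths_observed.csv"))
    write_count_table(deaths_rd, out("deaths_redistributed.csv"))
    fwrite(scn$covariates, out("covariates.csv"))
    fwrite(as.data.table(scn$graph$edges), out("adjacency.csv"))
    fwrite(scn$truth$rates, out("truth.csv"))
    write_summary_table(est, out("estimates.csv"))
    write_summary_table(disparities, out("disparities.csv"))
    fwrite(census_dt, out("census.csv"))
    cfg_out <- config
    cfg_out$params <- lapply(config$params, function(p) {
      p$beta0 <- as.list(p$beta0)
      p$gamma <- as.list(p$gamma)
      p
    })
    yaml::write_yaml(cfg_out, out("scenario_config.yaml"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("countymort")),
      root_seed = seed, stage_seeds = as.list(scn$seeds),
      n_draws = config$n_draws, rake_tol = config$rake_tol,
      fit_tol = config$fit_tol,
      masking_threshold = config$masking_threshold,
      stages = c("simulate", "redistribute", "fit", "adjust", "rake",
                 "summarise"),
      elapsed_seconds = round(proc.time()[3] - t_all, 2))
    yaml::write_yaml(manifest, out("manifest.yaml"))
  }
  invisible(result)
}

#' Bind draw cubes over disjoint strata
#'
#' @param ... [draw_cube()]s with identical draw counts and index
#'   columns.
#' @return A single [draw_cube()].
#' @export
cube_rbind <- function(...) {
  cubes <- list(...)
  nd <- unique(vapply(cubes, `[[`, 0L, "n_draws"))
  if (length(nd) != 1L) stop("draw counts differ")
  draw_cube(rbindlist(lapply(cubes, `[[`, "strata")),
            do.call(rbind, lapply(cubes, `[[`, "draws")))
}
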