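library(data.table)

# a desk-scale scenario for fast unit tests: 9 counties, 3 ages, 4 years
small_config <- function() {
  cfg <- default_scenario_config()
  cfg$n_counties <- 9L
  cfg$ages <- c("0-39", "40-69", "70+")
  cfg$age_standard_weights <- c(0.55, 0.35, 0.10)
  cfg$years <- 2015:2018
  cfg$size_range <- c(2e3, 5e4)
  cfg$n_draws <- 50L
  cfg$params <- lapply(cfg$params, function(p) { p$tau_v <- 4; p })
  cfg
}

# memoised: generated once per test run
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_scenario(small_config(), seed = 101)
    cache
  }
})

# full default scenario + pipeline run, shared by the acceptance tests
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(run_pipeline(default_scenario_config()))
    cache
  }
})

# a 2-county toy schema for hand-checked examples
toy_schema <- function(n_ages = 2L, n_years = 1L, races = c("Black", "White"),
                       n_counties = 2L) {
  strata_schema(
    counties = paste0("k", seq_len(n_counties)), races = races,
    sexes = "both",
    ages = paste0("a", seq_len(n_ages)),
    years = 2000L + seq_len(n_years) - 1L,
    causes = c("stomach_cancer", "other"))
}

toy_graph <- function(schema) {
  n <- length(schema$counties)
  edges <- if (n >= 2L)
    cbind(schema$counties[-n], schema$counties[-1L]) else
    matrix(character(), ncol = 2L)
  county_graph(schema$counties, edges)
}

# constant-population table for a toy schema
toy_population <- function(schema, value = 1000L) {
  grid <- CJ(county = schema$counties, race = schema$races,
             sex = schema$sexes, age = schema$ages, year = schema$years)
  grid[, value := value]
  count_table(grid, schema, kind = "population")
}

# deaths table from explicit (partial) rows; grid-completed with zeros
toy_deaths <- function(schema, rows) {
  count_table(rows, schema, kind = "deaths")
}

# a degenerate draw cube: constant rate per stratum replicated n_draws times
constant_cube <- function(strata, rates, n_draws = 2L) {
  draw_cube(strata, matrix(rep(rates, n_draws), nrow = length(rates)))
}
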