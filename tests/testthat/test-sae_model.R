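test_that("structure matrices match their definitions", {
  g <- generate_geography(4L, "grid")
  Q <- as.matrix(icar_structure(g))
  # degree matrix minus adjacency; every row sums to zero
  expect_equal(unname(diag(Q)), rep(2, 4))
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  expect_true(isSymmetric(Q))
  # RW1 over 3 time points: tridiagonal (1, 2, 1) / -1 pattern
  Q3 <- as.matrix(rw1_structure(3L))
  expect_equal(Q3, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  ev <- eigen(Q3, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 0, tolerance = 1e-12)
})

test_that("build_inputs assembles a complete grid and drops flat covariates", {
  sch <- toy_schema(n_ages = 2L, n_years = 3L)
  g <- toy_graph(sch)
  pop <- toy_population(sch, 500L)
  rows <- data.table(county = "k1", race = "Black", sex = "both",
                     age = "a1", year = 2000L, cause = "stomach_cancer",
                     value = 2L)
  deaths <- toy_deaths(sch, rows)
  cov <- data.table(county = sch$counties, flat = 1, ok = c(-1, 1))
  expect_warning(
    inputs <- build_inputs(deaths, pop, cov, g, sch,
                           cause = "stomach_cancer", sex = "both"),
    "zero-variance")
  expect_equal(nrow(inputs$strata), 2 * 2 * 2 * 3)
  expect_equal(length(inputs$gamma_idx), 1L)
  expect_equal(sum(inputs$D), 2)
  # blocks: u (rank 1), v (rank 1), w (rank 2), z (rank 2)
  expect_equal(vapply(inputs$blocks, `[[`, "", "name"),
               c("u", "v", "w", "z"))
  expect_equal(vapply(inputs$blocks, `[[`, 0L, "rank"), c(1L, 1L, 2L, 2L))
})

test_that("neg_log_posterior equals a brute-force direct summation", {
  sch <- toy_schema(n_ages = 2L, n_years = 2L)
  g <- toy_graph(sch)
  pop <- toy_population(sch, 800L)
  rows <- data.table(
    county = c("k1", "k1", "k2"), race = c("Black", "White", "Black"),
    sex = "both", age = c("a1", "a2", "a1"), year = 2000L,
    cause = "stomach_cancer", value = c(3L, 1L, 2L))
  deaths <- toy_deaths(sch, rows)
  inputs <- build_inputs(deaths, pop, NULL, g, sch,
                         cause = "stomach_cancer", sex = "both")
  set.seed(42)
  for (rep in 1:5) {
    par <- rnorm(inputs$n_par, sd = 0.5)
    expect_equal(neg_log_posterior(par, inputs),
                 brute_nlp(par, inputs, g, sch), tolerance = 1e-10)
  }
  expect_error(neg_log_posterior(rep(NA_real_, inputs$n_par), inputs),
               "non-finite")
})

test_that("the analytic gradient matches numerical differentiation", {
  sch <- toy_schema(n_ages = 2L, n_years = 2L)
  g <- toy_graph(sch)
  pop <- toy_population(sch, 800L)
  rows <- data.table(county = "k1", race = "Black", sex = "both",
                     age = "a1", year = 2000L, cause = "stomach_cancer",
                     value = 4L)
  inputs <- build_inputs(toy_deaths(sch, rows), pop, NULL, g, sch,
                         cause = "stomach_cancer", sex = "both")
  set.seed(7)
  par <- rnorm(inputs$n_par, sd = 0.3)
  g_an <- neg_log_posterior_grad(par, inputs)
  h <- 1e-6
  g_num <- vapply(seq_along(par), function(k) {
    e <- numeric(length(par)); e[k] <- h
    (neg_log_posterior(par + e, inputs) -
       neg_log_posterior(par - e, inputs)) / (2 * h)
  }, 0)
  expect_equal(g_an, g_num, tolerance = 1e-5)
})

test_that("pooled Poisson MLE is recovered without random effects", {
  # single county, race, age, year: no random-effect blocks survive
  sch <- strata_schema("k1", "White", "both", "a1", 2000L,
                       c("stomach_cancer", "other"))
  g <- county_graph("k1", matrix(character(), ncol = 2))
  pop <- toy_population(sch, 1000L)
  rows <- data.table(county = "k1", race = "White", sex = "both",
                     age = "a1", year = 2000L, cause = "stomach_cancer",
                     value = 3L)
  inputs <- build_inputs(toy_deaths(sch, rows), pop, NULL, g, sch,
                         cause = "stomach_cancer", sex = "both")
  expect_length(inputs$blocks, 0L)
  fit <- fit_map(inputs)
  expect_true(fit$converged)
  expect_equal(fit$par[1], log(3 / 1000), tolerance = 1e-8)
  # stationarity: gradient vanishes at m = D/P
  expect_lt(max(abs(neg_log_posterior_grad(fit$par, inputs))), 1e-6)
})

test_that("rate estimates are invariant to doubling population and deaths", {
  scn <- small_scenario()
  inputs <- build_inputs(scn$deaths_true, scn$population, NULL, scn$graph,
                         scn$schema, cause = "other", sex = "both")
  fit <- fit_map(inputs)
  pop2 <- copy(as.data.table(scn$population))[, value := value * 2L]
  pop2 <- count_table(pop2, scn$schema, kind = "population")
  d2 <- copy(as.data.table(scn$deaths_true))[, value := value * 2L]
  d2 <- count_table(d2, scn$schema, kind = "deaths")
  inputs2 <- build_inputs(d2, pop2, NULL, scn$graph, scn$schema,
                          cause = "other", sex = "both")
  fit2 <- fit_map(inputs2)
  eta1 <- drop(inputs$MB %*% fit$par[seq_len(inputs$K_eff)])
  eta2 <- drop(inputs2$MB %*% fit2$par[seq_len(inputs2$K_eff)])
  expect_equal(eta1, eta2, tolerance = 5e-3)
})

test_that("fixed effects are recovered within 3 posterior SDs", {
  cfg <- small_config()
  scn <- small_scenario()
  inputs <- build_inputs(scn$deaths_true, scn$population, scn$covariates,
                         scn$graph, scn$schema, cause = "other",
                         sex = "both")
  fit <- fit_map(inputs)
  expect_true(fit$converged)
  V <- chol2inv(chol(fit$H))
  sds <- sqrt(diag(V))
  truth <- c(cfg$params$other$beta0, cfg$params$other$gamma)
  est <- fit$par[c(inputs$beta_idx, inputs$gamma_idx)]
  expect_true(all(abs(est - truth) / sds[1:3] < 3))
})

test_that("posterior draws are seed-deterministic and centred at the mode", {
  scn <- small_scenario()
  inputs <- build_inputs(scn$deaths_true, scn$population, NULL, scn$graph,
                         scn$schema, cause = "other", sex = "both")
  fit <- fit_map(inputs)
  c1 <- draw_posterior(fit, n_draws = 20L, seed = 5)
  c2 <- draw_posterior(fit, n_draws = 20L, seed = 5)
  expect_identical(c1$draws, c2$draws)
  # enormous curvature: draws collapse onto the mode surface
  fit_tight <- fit
  fit_tight$H <- fit$H * 1e8
  c3 <- draw_posterior(fit_tight, n_draws = 10L, seed = 5)
  mode_rate <- exp(drop(inputs$MB %*% fit$par[seq_len(inputs$K_eff)]))
  expect_lt(max(abs(c3$draws - mode_rate) / mode_rate), 1e-3)
  # draw mean of the linear predictor approaches the mode
  c4 <- draw_posterior(fit, n_draws = 5000L, seed = 6)
  eta_bar <- rowMeans(log(c4$draws))
  eta_mode <- drop(inputs$MB %*% fit$par[seq_len(inputs$K_eff)])
  sdv <- apply(log(c4$draws), 1L, sd) / sqrt(5000)
  expect_true(mean(abs(eta_bar - eta_mode) < 4 * sdv) > 0.95)
  # broken curvature is reported with its eigenvalue
  fit_bad <- fit
  fit_bad$H <- fit$H - diag(1e6, nrow(fit$H))
  expect_error(suppressWarnings(draw_posterior(fit_bad, 5L, seed = 1)),
               "eigenvalue")
})

test_that("estimated surfaces are smoother than the raw death rates", {
  scn <- small_scenario()
  inputs <- build_inputs(scn$deaths_true, scn$population, NULL, scn$graph,
                         scn$schema, cause = "stomach_cancer", sex = "both")
  fit <- fit_map(inputs)
  eta <- drop(inputs$MB %*% fit$par[seq_len(inputs$K_eff)])
  est <- exp(eta)
  raw <- ifelse(inputs$P > 0, inputs$D / inputs$P, 0)
  # variance around the race-year mean surface
  key <- paste(inputs$strata$race, inputs$strata$year)
  resid_var <- function(x) {
    mu <- ave(x, key)
    mean((x - mu)^2)
  }
  expect_lt(resid_var(est), resid_var(raw))
})
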