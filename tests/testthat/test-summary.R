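test_that("age-standardisation is the weighted sum over age groups", {
  strata <- CJ(county = "k1", race = "White", sex = "both",
               age = c("a1", "a2"), year = 2019L)
  cube <- constant_cube(strata, c(2e-5, 4e-5))
  std <- age_standard(c("a1", "a2"), c(0.5, 0.5))
  asr <- age_standardise(cube, std)
  expect_equal(asr$draws[1, 1], 3e-5)
  # constant rate across ages: ASR equals the rate for any valid standard
  cube2 <- constant_cube(strata, c(5e-5, 5e-5))
  std2 <- age_standard(c("a1", "a2"), c(0.91, 0.09))
  expect_equal(age_standardise(cube2, std2)$draws[1, 1], 5e-5,
               tolerance = 1e-15)
  # 5-age toy against a hand-computed weighted sum
  strata5 <- CJ(county = "k1", race = "White", sex = "both",
                age = paste0("a", 1:5), year = 2019L)
  rates <- c(1, 2, 4, 8, 16) * 1e-5
  w <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  cube5 <- constant_cube(strata5, rates)
  expect_equal(age_standardise(cube5, age_standard(paste0("a", 1:5), w))
               $draws[1, 1], sum(w * rates), tolerance = 1e-12)
  # missing weight errors
  expect_error(age_standardise(cube5, std), "missing weight")
})

test_that("population-weighted aggregation collapses dimensions correctly", {
  sch <- toy_schema(n_ages = 1L)
  strata <- CJ(county = c("k1", "k2"), race = "Black", sex = "both",
               age = "a1", year = 2000L)
  cube <- constant_cube(strata, c(2e-5, 4e-5))
  pop <- CJ(county = c("k1", "k2"), race = c("Black", "White"),
            sex = "both", age = "a1", year = 2000L)
  pop[, value := ifelse(race == "Black", ifelse(county == "k1", 100L, 300L),
                        50L)]
  pop <- count_table(pop, sch, kind = "population")
  agg <- aggregate_weighted(cube, pop, group_by = c("race", "sex", "age",
                                                    "year"))
  expect_equal(agg$draws[1, 1], (100 * 2e-5 + 300 * 4e-5) / 400)
  # single stratum: identity
  one <- cube_subset(cube, county = "k1")
  agg1 <- aggregate_weighted(one, pop, group_by = c("county", "race",
                                                    "sex", "age", "year"))
  expect_equal(agg1$draws, one$draws)
  # implied deaths conserved: sum(P*m) national = sum over counties
  expect_equal(agg$draws[1, 1] * 400, 100 * 2e-5 + 300 * 4e-5)
})

test_that("draw summaries use the mean and interpolated percentiles", {
  strata <- data.table(county = "k1", race = "White", year = 2019L)
  cube <- draw_cube(strata, matrix(seq_len(1000) / 1e5, nrow = 1))
  s <- summarise_draws(cube, scale = 1e5)
  # draws 1..1000: 2.5th percentile by linear interpolation = 25.975
  expect_equal(s$lower, 25.975)
  expect_equal(s$upper, 975.025)
  expect_equal(s$mean, 500.5)
  # invariant to draw order
  cube2 <- draw_cube(strata, matrix(sample(seq_len(1000)) / 1e5, nrow = 1))
  expect_equal(summarise_draws(cube2, scale = 1e5), s)
  # constant draws collapse to a point
  cc <- constant_cube(strata, 4.2e-5, n_draws = 10L)
  sc <- summarise_draws(cc)
  expect_equal(unlist(sc[, .(mean, lower, upper)]), rep(4.2, 3),
               ignore_attr = TRUE)
  expect_error(summarise_draws(constant_cube(strata, 1e-5, 1L)),
               "at least 2 draws")
})

test_that("percent change is computed draw-wise", {
  strata0 <- data.table(county = "k1", race = "White", year = 2000L)
  strata1 <- data.table(county = "k1", race = "White", year = 2019L)
  m0 <- matrix(c(4e-5, 6e-5, 8e-5), nrow = 1)
  halves <- draw_cube(strata1, m0 / 2)
  base <- draw_cube(strata0, m0)
  pc <- percent_change(base, halves)
  expect_equal(pc$mean, -50)
  expect_equal(pc$lower, -50)
  # identical cubes: 0 with zero-width interval
  pc0 <- percent_change(base, draw_cube(strata1, m0))
  expect_equal(unlist(pc0[, .(mean, lower, upper)]), rep(0, 3),
               ignore_attr = TRUE)
  # 3-draw toy against direct arithmetic
  m1 <- matrix(c(3e-5, 9e-5, 8e-5), nrow = 1)
  pc3 <- percent_change(base, draw_cube(strata1, m1))
  byhand <- 100 * (c(3, 9, 8) - c(4, 6, 8)) / c(4, 6, 8)
  expect_equal(pc3$mean, mean(byhand))
  expect_error(percent_change(draw_cube(strata0, m0 * 0), halves), "zero")
})

test_that("disparities reproduce the printed worked example", {
  strata_g <- data.table(county = "us", race = "Black", year = 2019L)
  strata_r <- data.table(county = "us", race = "White", year = 2019L)
  g <- constant_cube(strata_g, 6.8e-5)
  r <- constant_cube(strata_r, 3.5e-5)
  d <- disparity(g, r)
  expect_equal(d[measure == "diff", mean], 3.3, tolerance = 1e-12)
  expect_equal(round(d[measure == "ratio", mean], 1), 1.9)
  # identical cubes: no disparity, not significant
  d0 <- disparity(g, constant_cube(strata_r, 6.8e-5))
  expect_equal(d0[measure == "diff", mean], 0)
  expect_equal(d0[measure == "ratio", mean], 1)
  expect_false(any(d0$significant))
  # all difference draws positive: significant
  set.seed(4)
  gg <- draw_cube(strata_g, matrix(6e-5 + abs(rnorm(200)) * 1e-6, 1))
  rr <- draw_cube(strata_r, matrix(rep(3e-5, 200), 1))
  expect_true(all(disparity(gg, rr)$significant))
  expect_error(disparity(gg, draw_cube(strata_r, matrix(rep(0, 200), 1))),
               "strictly positive")
})

test_that("significance is monotone in the shift between the cubes", {
  strata_g <- data.table(county = "k1", race = "Black", year = 2019L)
  strata_r <- data.table(county = "k1", race = "White", year = 2019L)
  set.seed(9)
  base <- rnorm(500, 5e-5, 5e-6)
  r <- draw_cube(strata_r, matrix(base, 1))
  prob_gt <- function(shift) {
    g <- draw_cube(strata_g, matrix(rev(base) + shift, 1))
    d <- disparity(g, r)[measure == "diff"]
    d$significant
  }
  shifts <- c(0, 2e-6, 5e-6, 1e-5, 2e-5)
  sig <- vapply(shifts, prob_gt, NA)
  # once significant, larger shifts stay significant
  expect_true(all(diff(as.integer(sig)) >= 0))
  expect_true(sig[length(sig)])
})

test_that("masking is strict at the population threshold", {
  sch <- toy_schema(n_ages = 1L, n_years = 2L, n_counties = 3L)
  pop <- CJ(county = paste0("k", 1:3), race = c("Black", "White"),
            sex = "both", age = "a1", year = c(2000L, 2001L))
  # Black mean annual pop: k1 999.5 -> masked; k2 1000 -> kept; k3 400
  pop[, value := 5000L]
  pop[race == "Black" & county == "k1", value := c(999L, 1000L)]
  pop[race == "Black" & county == "k2", value := 1000L]
  pop[race == "Black" & county == "k3", value := 400L]
  pop <- count_table(pop, sch, kind = "population")
  st <- CJ(county = paste0("k", 1:3), race = "Black", year = c(2000L, 2001L))
  st[, `:=`(mean = 5, lower = 4, upper = 6, measure = "rate",
            masked = FALSE)]
  out <- apply_masking(st, pop, threshold = 1000)
  expect_equal(out[county == "k1", unique(masked)], TRUE)
  expect_equal(out[county == "k2", unique(masked)], FALSE)
  expect_equal(out[county == "k3", unique(masked)], TRUE)
  # masked rows blanked in every year
  expect_true(all(is.na(out[county == "k1", mean])))
  # threshold 0 masks nothing
  out0 <- apply_masking(st, pop, threshold = 0)
  expect_false(any(out0$masked))
  # comparison rows masked if either group falls below the threshold
  both <- apply_masking(st, pop, threshold = 1200,
                        races = c("Black", "White"))
  expect_true(all(both$masked))  # Black below 1200 everywhere
})

test_that("the county disparity census counts and percentages", {
  disp <- data.table(
    county = paste0("k", 1:3), race = "AIAN", year = 2019L,
    mean = c(1.2, 1.1, 0.9), lower = 1, upper = 2, measure = "ratio",
    significant = c(TRUE, FALSE, FALSE), masked = FALSE)
  cz <- disparity_census(disp)
  expect_equal(cz$n_total, 3L)
  expect_equal(cz$n_higher, 2L)
  expect_equal(cz$n_significant, 1L)
  expect_equal(cz$pct_higher, 66.7)
  expect_equal(cz$pct_significant, 33.3)
  # all higher and significant
  disp2 <- copy(disp)[, `:=`(mean = 1.5, significant = TRUE)]
  cz2 <- disparity_census(disp2)
  expect_equal(c(cz2$pct_higher, cz2$pct_significant), c(100, 100))
  # masked counties drop out of the denominator
  disp3 <- copy(disp)[county == "k3", masked := TRUE]
  expect_equal(disparity_census(disp3)$n_total, 2L)
  expect_error(disparity_census(disp[masked == TRUE]), "no unmasked")
})

test_that("aggregation before age-standardisation matches the direct route", {
  scn <- small_scenario()
  # any rate cube over the full grid works; use truth as a surface
  tr <- scn$truth$rates[cause == "stomach_cancer"]
  cube <- draw_cube(tr[, .(county, race, sex, age, year)],
                    matrix(rep(tr$rate, 2), ncol = 2))
  std <- scn$standard
  agg <- aggregate_weighted(cube, scn$population,
                            group_by = c("race", "sex", "age", "year"))
  asr1 <- age_standardise(agg, std)
  # direct: standardise the population-weighted age-specific rates
  pop <- as.data.table(scn$population)
  dt <- merge(tr, pop, by = c("county", "race", "sex", "age", "year"))
  direct <- dt[, .(m = sum(rate * value) / sum(value)),
               by = .(race, sex, age, year)]
  direct <- merge(direct, as.data.table(std), by.x = "age", by.y = "age")
  direct <- direct[, .(asr = sum(m * weight)), by = .(race, sex, year)]
  got <- copy(asr1$strata)[, est := asr1$draws[, 1]]
  m <- merge(got, direct, by = c("race", "sex", "year"))
  expect_equal(m$est, m$asr, tolerance = 1e-12)
})

test_that("ASR is invariant to splitting a county at identical rates", {
  sch <- toy_schema(n_ages = 2L, n_counties = 2L, races = "White")
  strata <- CJ(county = c("k1", "k2"), race = "White", sex = "both",
               age = c("a1", "a2"), year = 2000L)
  rates <- c(2e-5, 6e-5, 2e-5, 6e-5)  # same age profile in both counties
  cube <- constant_cube(strata, rates)
  pop <- CJ(county = c("k1", "k2"), race = "White", sex = "both",
            age = c("a1", "a2"), year = 2000L)
  pop[, value := c(300L, 200L, 700L, 800L)]
  pop <- count_table(pop, sch, kind = "population")
  std <- age_standard(c("a1", "a2"), c(0.6, 0.4))
  # aggregate the two counties, then standardise
  agg <- aggregate_weighted(cube, pop, group_by = c("race", "sex", "age",
                                                    "year"))
  asr_all <- age_standardise(agg, std)$draws[1, 1]
  asr_single <- age_standardise(cube_subset(cube, county = "k1"), std)
  expect_equal(asr_all, asr_single$draws[1, 1], tolerance = 1e-12)
})
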